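# brute-force oracle: all (Lys NZ, candidate functional atom) pairs
oracle_env <- function(st, chain) {
  a <- st$atoms[st$atoms$chain == chain & !st$atoms$het, ]
  acid_set <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
  base_set <- list(HIS = c("ND1", "NE2"), ARG = c("NE", "NH1", "NH2"),
                   LYS = "NZ")
  nz <- a[a$resname == "LYS" & a$name == "NZ", ]
  out <- list()
  for (i in seq_len(nrow(nz))) {
    best_a <- Inf; best_b <- Inf
    for (j in seq_len(nrow(a))) {
      at <- a[j, ]
      d <- euclid(c(nz$x[i], nz$y[i], nz$z[i]), c(at$x, at$y, at$z))
      if (!is.null(acid_set[[at$resname]]) &&
          at$name %in% acid_set[[at$resname]]) best_a <- min(best_a, d)
      if (!is.null(base_set[[at$resname]]) &&
          at$name %in% base_set[[at$resname]] &&
          !(at$resname == "LYS" && at$resseq == nz$resseq[i]))
        best_b <- min(best_b, d)
    }
    out[[i]] <- c(if (is.finite(best_a)) best_a else NA_real_,
                  if (is.finite(best_b)) best_b else NA_real_)
  }
  do.call(rbind, out)
}

test_that("constructed Lys-Asp pair reports the exact distance", {
  env <- lysine_environment(build_toy_structure("lys_acid_pair",
                                                list(d = 5)), "A")
  expect_equal(env$acid_dist, 5)
  expect_equal(env$nearest_acid, "Asp_2")
  expect_true(is.na(env$base_dist))
})

test_that("environments match the all-pairs brute-force oracle", {
  for (seed in 1:25) {
    st <- rand_glyc_structure(seed)
    env <- lysine_environment(st, "A")
    want <- oracle_env(st, "A")
    expect_equal(env$acid_dist, want[, 1])
    expect_equal(env$base_dist, want[, 2])
  }
})

test_that("classification uses a strict cutoff", {
  env <- data.frame(lysine = 1:2, acid_dist = c(9.99, 10.00),
                    base_dist = c(NA, NA))
  calls <- classify_glycation(env, cutoff = 10)
  expect_equal(calls$glycable, c(TRUE, FALSE))
  expect_equal(calls$supporting_distance, c(9.99, 10.00))
})

test_that("transcribed per-lysine table reproduces the published counts", {
  g <- FIX$glycation
  for (prot in c("3K4Q", "1QFX_A")) {
    sub <- g[g$protein == prot, ]
    calls <- classify_glycation(sub)
    expect_equal(calls$glycable, sub$distance_call)
  }
  expect_equal(sum(classify_glycation(g[g$protein == "3K4Q", ])$glycable),
               14L)
  expect_equal(sum(classify_glycation(g[g$protein == "1QFX_A", ])$glycable),
               10L)
})

test_that("glycable set is monotone in the cutoff", {
  for (seed in 1:10) {
    st <- rand_glyc_structure(seed + 100)
    env <- lysine_environment(st, "A")
    cuts <- c(2, 5, 8, 10, 15, 30)
    sets <- lapply(cuts, function(cc)
      classify_glycation(env, cc)$lysine[classify_glycation(env,
                                                            cc)$glycable])
    for (k in seq_along(cuts)[-1])
      expect_true(all(sets[[k - 1]] %in% sets[[k]]))
  }
})

test_that("agreement statistics: identity, disjoint and universe checks", {
  a <- data.frame(lysine = 1:4, glycable = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(compare_predictions(a, a)$fraction_b_of_a, 100)
  expect_equal(compare_predictions(a, a)$fraction_a_with_support, 100)
  b <- data.frame(lysine = 1:4, glycable = c(FALSE, FALSE, TRUE, TRUE))
  st <- compare_predictions(a, b)
  expect_equal(st$n_overlap, 0L)
  expect_equal(st$fraction_b_of_a, 0)
  expect_error(compare_predictions(a, data.frame(lysine = 2:5,
                                                 glycable = TRUE)),
               "universe")
})

test_that("external calls round-trip through the TSV reader", {
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(data.frame(lysine = c(68, 71), glycable = c(TRUE,
                                                                 FALSE)),
                     f, sep = "\t", quote = FALSE, row.names = FALSE)
  calls <- read_glycation_calls(f)
  expect_equal(calls$method, rep("external", 2))
  expect_equal(calls$glycable, c(TRUE, FALSE))
})

test_that("missing chain and NZ-less lysines are handled", {
  st <- build_toy_structure("lys_acid_pair", list(d = 5))
  expect_error(lysine_environment(st, "Q"), "chain")
  a <- st$atoms
  a <- a[!(a$resname == "LYS" & a$name == "NZ"), ]
  a <- rbind(a, protchar:::atom_row(0, "CA", "LYS", "A", 9, c(1, 1, 1), "C"))
  expect_warning(lysine_environment(protchar:::as_structure(a), "A"),
                 "skipped")
})
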