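# exhaustive interface oracle: loop over every heavy-atom pair
oracle_interface <- function(st, ca, cb, cutoff) {
  a <- st$atoms[st$atoms$chain == ca & st$atoms$element != "H" &
                  !st$atoms$water, ]
  b <- st$atoms[st$atoms$chain == cb & st$atoms$element != "H" &
                  !st$atoms$water, ]
  hits <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    d <- euclid(c(a$x[i], a$y[i], a$z[i]), c(b$x[j], b$y[j], b$z[j]))
    key <- paste(a$resseq[i], b$resseq[j])
    if (d <= cutoff)
      hits[[key]] <- min(d, if (is.null(hits[[key]])) Inf else hits[[key]])
  }
  hits
}

test_that("constructed contact pair is found at its exact distance", {
  st <- build_toy_structure("two_chain_contact", list(d = 3.5))
  out <- interface_residues(st, "A", "B", cutoff = 4)
  expect_equal(nrow(out), 1L)
  expect_equal(out$min_distance, 3.5)
  expect_equal(nrow(interface_residues(st, "A", "B", cutoff = 3.4)), 0L)
  expect_error(interface_residues(st, "A", "A"), "differ")
  expect_error(interface_residues(st, "A", "Z"), "chain")
})

test_that("interface detection equals the exhaustive pair scan", {
  for (seed in 1:20) {
    st <- rand_dimer(seed)
    out <- interface_residues(st, "A", "B", cutoff = 5)
    want <- oracle_interface(st, "A", "B", 5)
    expect_equal(nrow(out), length(want))
    for (r in seq_len(nrow(out))) {
      key <- paste(out$resseq_a[r], out$resseq_b[r])
      expect_equal(out$min_distance[r], want[[key]])
    }
  }
})

test_that("interface detection is symmetric in the chains", {
  st <- rand_dimer(31)
  ab <- interface_residues(st, "A", "B", cutoff = 6)
  ba <- interface_residues(st, "B", "A", cutoff = 6)
  expect_equal(nrow(ab), nrow(ba))
  expect_equal(sort(paste(ab$resseq_a, ab$resseq_b)),
               sort(paste(ba$resseq_b, ba$resseq_a)))
  expect_equal(sort(ab$min_distance), sort(ba$min_distance))
})

test_that("constructed hydrogen bond is detected with distance and angle", {
  st <- build_toy_structure("hbond_complex", list(d = 3.0, angle = 180))
  lig <- select_atoms(st, het = TRUE)
  hb <- find_pose_hbonds(st, lig)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$distance, 3.0)
  expect_equal(hb$angle, 180)
  expect_equal(hb$donor_side, "receptor")
  expect_equal(hb$receptor_residue, "Arg_1")
  # same geometry at 4.0 A: outside the cutoff
  st4 <- build_toy_structure("hbond_complex", list(d = 4.0, angle = 180))
  expect_equal(nrow(find_pose_hbonds(st4, select_atoms(st4, het = TRUE))),
               0L)
  # bad angle with an explicit hydrogen is rejected
  st90 <- build_toy_structure("hbond_complex", list(d = 3.0, angle = 90))
  expect_equal(nrow(find_pose_hbonds(st90, select_atoms(st90, het = TRUE))),
               0L)
})

test_that("bond set shrinks monotonically with the distance cutoff", {
  st <- build_toy_structure("hbond_complex", list(d = 3.2, angle = 160))
  lig <- select_atoms(st, het = TRUE)
  n_prev <- Inf
  for (cc in c(3.5, 3.3, 3.1, 2.5)) {
    n <- nrow(find_pose_hbonds(st, lig, dist_cutoff = cc))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("ligand without N/O atoms warns and returns empty", {
  st <- build_toy_structure("hbond_complex", list(d = 3.0))
  lig <- select_atoms(st, het = TRUE)
  lig <- lig[lig$element == "C", , drop = FALSE]
  expect_warning(hb <- find_pose_hbonds(st, lig), "no N/O")
  expect_equal(nrow(hb), 0L)
})

test_that("pose summary is the residue multiset convention", {
  hb <- data.frame(receptor_atom = letters[1:8], ligand_atom = letters[1:8],
                   receptor_residue = c("Arg_58", "His_59", "Arg_62",
                                        "Arg_62", "Arg_142", "Arg_142",
                                        "His_338", "Asp_339"),
                   distance = seq(2.6, 3.3, by = 0.1), angle = NA,
                   donor_side = "receptor", stringsAsFactors = FALSE)
  sm <- summarize_pose(hb)
  expect_equal(sm$n_bonds, 8L)
  expect_length(sm$residues, 8L)   # repeats retained, one entry per bond
  expect_equal(sum(sm$residues == "Arg_62"), 2L)
  expect_equal(summarize_pose(hb[0, ])$n_bonds, 0L)
})
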