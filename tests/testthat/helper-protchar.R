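# Shared fixtures: parameter tables and printed-table fixtures are loaded
# once per test run; random generators used across files live here.
TABS <- load_tables()
FIX <- table_fixtures()

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

rand_seq <- function(n, seed, id = "rnd") {
  withr::with_seed(seed, protein_sequence(
    paste(sample(AA20, n, replace = TRUE), collapse = ""), id = id))
}

rand_comp <- function(seed, max_count = 20L) {
  withr::with_seed(seed, {
    k <- sample(2:20, 1)
    letters <- sample(AA20, k)
    composition_table(stats::setNames(sample.int(max_count, k,
                                                 replace = TRUE), letters))
  })
}

# random toy structure for distance oracles: lysines plus acid/base
# side-chain atoms scattered in a box
rand_glyc_structure <- function(seed, n_lys = 4L, n_other = 10L) {
  withr::with_seed(seed, {
    rows <- list()
    xyz <- function() runif(3, 0, 25)
    for (i in seq_len(n_lys))
      rows[[length(rows) + 1]] <-
        protchar:::atom_row(0, "NZ", "LYS", "A", i, xyz(), "N")
    pool <- list(c("ASP", "OD1", "O"), c("ASP", "OD2", "O"),
                 c("GLU", "OE1", "O"), c("GLU", "OE2", "O"),
                 c("HIS", "ND1", "N"), c("HIS", "NE2", "N"),
                 c("ARG", "NH1", "N"), c("ARG", "NE", "N"),
                 c("SER", "OG", "O"), c("ALA", "CB", "C"))
    for (j in seq_len(n_other)) {
      p <- pool[[sample(length(pool), 1)]]
      rows[[length(rows) + 1]] <-
        protchar:::atom_row(0, p[2], p[1], "A", n_lys + j, xyz(), p[3])
    }
    protchar:::as_structure(do.call(rbind, rows))
  })
}

# random two-chain structure for interface oracles
rand_dimer <- function(seed, n_a = 6L, n_b = 6L) {
  withr::with_seed(seed, {
    rows <- list()
    for (i in seq_len(n_a))
      rows[[length(rows) + 1]] <-
        protchar:::atom_row(0, "CA", "GLY", "A", i, runif(3, 0, 12), "C")
    for (i in seq_len(n_b))
      rows[[length(rows) + 1]] <-
        protchar:::atom_row(0, "CA", "GLY", "B", i, runif(3, 0, 12), "C")
    protchar:::as_structure(do.call(rbind, rows))
  })
}

euclid <- function(a, b) sqrt(sum((a - b)^2))
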