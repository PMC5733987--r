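# independent dense-grid oracle for the isoelectric point: two-stage scan
# over a pure pH grid, no bisection involved
grid_pi <- function(comp, nterm) {
  q <- function(ph) protchar:::net_charge(comp, nterm, TABS, ph)
  coarse <- seq(0, 14, by = 0.01)
  p0 <- coarse[which.min(abs(q(coarse)))]
  fine <- seq(max(0, p0 - 0.02), min(14, p0 + 0.02), by = 1e-5)
  fine[which.min(abs(q(fine)))]
}

test_that("molecular weight: limits, additivity and mass-sum oracle", {
  expect_equal(molecular_weight(composition_table(integer(0)), TABS),
               18.02, tolerance = 1e-3)
  # free glycine: independent sum of its atomic composition C2H5NO2
  gly <- 2 * 12.011 + 5 * 1.008 + 14.007 + 2 * 15.999
  expect_equal(molecular_weight(composition_table(c(G = 1)), TABS), gly,
               tolerance = 0.01)
  a <- rand_comp(1); b <- rand_comp(2)
  ab <- composition_table(a$counts + b$counts)
  expect_equal(molecular_weight(ab, TABS),
               molecular_weight(a, TABS) + molecular_weight(b, TABS) -
                 TABS$water_mass)
})

test_that("isoelectric point zeroes the net charge (grid oracle)", {
  gg <- composition(protein_sequence("GG"))
  pi_gg <- isoelectric_point(gg, "G", TABS)
  expect_lt(abs(protchar:::net_charge(gg, "G", TABS, pi_gg)), 1e-3)
  for (seed in 1:50) {
    cmp <- rand_comp(seed)
    nt <- names(cmp$counts)[cmp$counts > 0][1]
    expect_equal(isoelectric_point(cmp, nt, TABS), grid_pi(cmp, nt),
                 tolerance = 1e-3)
  }
  expect_error(isoelectric_point(composition_table(c(A = 1)), "B", TABS),
               "standard")
})

test_that("charged counts follow the Asp+Glu / Arg+Lys convention", {
  polyg <- composition(protein_sequence(strrep("G", 10)))
  expect_equal(unlist(charged_counts(polyg)),
               c(neg_count = 0, neg_pct = 0, pos_count = 0, pos_pct = 0))
  ch <- charged_counts(FIX$compositions[["3K4Q"]])
  expect_equal(ch$neg_count, 51L)  # His not counted as positive
  expect_equal(ch$pos_count, 34L)
})

test_that("gravy matches the expansion oracle and the scale bounds", {
  expect_equal(gravy(composition_table(c(I = 1)), TABS), 4.5)
  for (seed in 1:10) {
    cmp <- rand_comp(seed)
    expanded <- rep(names(cmp$counts), cmp$counts)
    expect_equal(gravy(cmp, TABS), mean(TABS$kd_scale[expanded]))
  }
  # composition sufficiency: sequence and composition routes agree
  s <- rand_seq(90, seed = 3)
  expect_equal(gravy(s, TABS), gravy(composition(s), TABS))
})

test_that("aliphatic index formula", {
  polya <- composition(protein_sequence(strrep("A", 25)))
  expect_equal(aliphatic_index(polya, TABS), 100)
  cmp <- rand_comp(11)
  x <- function(a) 100 * cmp$counts[[a]] / cmp$length
  expect_equal(aliphatic_index(cmp, TABS),
               x("A") + 2.9 * x("V") + 3.9 * (x("I") + x("L")))
  s <- rand_seq(60, seed = 5)
  expect_equal(aliphatic_index(s, TABS),
               aliphatic_index(composition(s), TABS))
})

test_that("instability index: dipeptide formula and label threshold", {
  for (xy in c("AG", "WW", "PK")) {
    s <- protein_sequence(xy)
    l <- strsplit(xy, "")[[1]]
    expect_equal(instability_index(s, TABS)$value,
                 5 * TABS$diwv[l[1], l[2]])
  }
  s <- rand_seq(50, seed = 9)
  l <- strsplit(s$residues, "")[[1]]
  tot <- 0
  for (i in 1:49) tot <- tot + TABS$diwv[l[i], l[i + 1]]
  ii <- instability_index(s, TABS)
  expect_equal(ii$value, 10 / 50 * tot)
  expect_equal(ii$stability_label, if (ii$value > 40) "unstable" else
    "stable")
  expect_error(instability_index(protein_sequence("A"), TABS), "at least 2")
})

test_that("N-end-rule lookup matches the published triplets", {
  expect_equal(unname(estimated_half_life("A", TABS)),
               c("4.4 hours", ">20 hours", ">10 hours"))
  expect_equal(unname(estimated_half_life("F", TABS)),
               c("1.1 hours", "3 min", "2 min"))
  expect_error(estimated_half_life("B", TABS), "unknown residue")
})

test_that("physchem report is internally consistent", {
  s <- rand_seq(120, seed = 21)
  rep <- physchem_report(s, tables = TABS)
  expect_equal(rep$neg_pct, 100 * rep$neg_count / rep$length)
  expect_equal(rep$mw_kda, rep$mw_da / 1000)
  expect_true(rep$pi > 0 && rep$pi < 14)
  expect_equal(rep$stability_label,
               if (rep$instability_index > 40) "unstable" else "stable")
})
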