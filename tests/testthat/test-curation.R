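test_that("strain consensus is unanimity with missing calls ignored", {
  geno <- toy_geno(list(m1 = c("A", "A"), m2 = c("A", "G"), m3 = c("A", "N"),
                        m4 = c("N", "N")),
                   samples = c("r1", "r2"))
  cons <- consensus_strains(geno, c(r1 = "S", r2 = "S"))
  expect_equal(unname(cons["S", ]), c("A", "N", "A", "N"))
  expect_true(attr(cons, "conflict")["S", "m2"])
  expect_false(attr(cons, "conflict")["S", "m4"])

  expect_error(consensus_strains(geno, c(r1 = "S", r9 = "S")), "r9")
})

test_that("mark_match keeps only markers shared by parents and offspring", {
  tab <- toy_table(list(m1 = c("A", "G"), m2 = c("C", "T")),
                   p1 = c("A", "C"), p2 = c("G", "T"))
  out <- mark_match(tab, parent_marker_ids = "m1")
  expect_equal(out$flag_match, c("pass", "fail"))

  expect_true(all(mark_match(tab, c("m1", "m2"))$flag_match == "pass"))
  expect_true(all(mark_match(tab, character())$flag_match == "fail"))
})

test_that("mark_match excludes markers missing from the annotation", {
  geno <- toy_geno(list(m1 = c("A", "G"), m_unannotated = c("C", "T")))
  tab <- build_marker_table(geno, toy_ann("m1"),
                            toy_parents(c("m1", "m_unannotated"),
                                        c("A", "C"), c("G", "T")))
  expect_equal(tab$chr[tab$marker == "m_unannotated"], "unknown")
  out <- mark_match(tab, c("m1", "m_unannotated"))
  expect_equal(out$flag_match[out$marker == "m_unannotated"], "fail")
  expect_equal(out$reason[out$marker == "m_unannotated"], "match:unmappable")
})

test_that("mark_allele fails the parent-monomorphic/offspring-polymorphic pattern", {
  # the six dataset-1 markers whose parents share one allele while two
  # alleles segregate in the offspring
  cases <- list(
    S6J017555686 = list(p = "C", sgi = c("T", "C")),
    S6J113080150 = list(p = "G", sgi = c("A", "G")),
    gJAX00038569 = list(p = "C", sgi = c("T", "C")),
    mUNC21540855 = list(p = "C", sgi = c("A", "C")),
    gUNC21555204 = list(p = "T", sgi = c("T", "C")),
    gUNC21596600 = list(p = "A", sgi = c("A", "G"))
  )
  calls <- lapply(cases, function(x) c(x$sgi, x$sgi, "H", "N"))
  tab <- toy_table(calls, p1 = vapply(cases, `[[`, "", "p"),
                   p2 = vapply(cases, `[[`, "", "p"))
  out <- mark_allele(tab, cross_type("F2"), filter_config())
  expect_true(all(out$flag_allele == "fail"))
  expect_true(all(out$reason == "allele:parents_monomorphic"))
  # none survive to encoding
  enc <- encode_genotypes(out, toy_geno(calls), cross_type("F2"))
  expect_equal(ncol(enc$geno), 0)
})

test_that("mark_allele passes fully consistent markers and applies rules i/iii/v", {
  tab <- toy_table(list(ok = c("A", "H", "G"),
                        nopar = c("A", "H", "G"),
                        foreign = c("A", "T", "G")),
                   p1 = c("A", "N", "A"), p2 = c("G", "N", "G"))
  out <- mark_allele(tab, cross_type("F2"), filter_config())
  expect_equal(out$flag_allele,
               c("pass", "fail", "fail"))
  expect_equal(out$reason[2:3],
               c("allele:parents_missing", "allele:foreign_allele"))

  # parNH strict: one missing parent fails instead of being imputed
  tab2 <- toy_table(list(m = c("A", "G", "H")), p1 = "A", p2 = "N")
  strict <- mark_allele(tab2, cross_type("F2"),
                        filter_config(parNH_strict = TRUE))
  expect_equal(strict$flag_allele, "fail")
  expect_equal(strict$reason, "allele:parent_NH")
  # and a heterozygous parent fails too
  tab3 <- toy_table(list(m = c("A", "G")), p1 = "A", p2 = "H")
  expect_equal(mark_allele(tab3, cross_type("F2"),
                           filter_config(parNH_strict = TRUE))$flag_allele,
               "fail")
})

test_that("backcross wrong-allele homozygotes fail mark_allele", {
  tab <- toy_table(list(m = c("A", "H", "G", "A")), p1 = "A", p2 = "G")
  out <- mark_allele(tab, cross_type("N2", recurrent = "p1"), filter_config())
  expect_equal(out$flag_allele, "fail")
  expect_equal(out$reason, "allele:wrong_homozygote")
  # the same data is a perfectly fine intercross marker
  expect_equal(mark_allele(tab, cross_type("F2"), filter_config())$flag_allele,
               "pass")
  # tolerance can admit isolated wrong homozygotes
  tol <- mark_allele(tab, cross_type("N2", recurrent = "p1"),
                     filter_config(wrong_homo_tol = 1))
  expect_equal(tol$flag_allele, "pass")
})

test_that("an N2 cross without a recurrent parent is rejected at construction", {
  expect_error(cross_type("N2"), "recurrent")
})

test_that("mark_na applies a strict > threshold", {
  calls_90 <- c(rep("N", 90), rep("A", 43), rep("G", 43))   # 51.1% missing
  calls_88 <- c(rep("N", 88), rep("A", 44), rep("G", 44))   # exactly 50%
  tab <- toy_table(list(over = calls_90, at = calls_88),
                   p1 = c("A", "A"), p2 = c("G", "G"))
  out <- mark_na(tab, filter_config())
  expect_equal(out$flag_na, c("fail", "pass"))

  zero <- mark_na(tab, filter_config(na_max = 0))
  expect_equal(zero$flag_na, c("fail", "fail"))
})

test_that("mark_poly drops monomorphic and information-free markers", {
  tab <- toy_table(list(mono = c("A", "A", "A", "N"),
                        seg = c("A", "H", "A", "A"),
                        allH = c("H", "H", "H", "H"),
                        allN = c("N", "N", "N", "N")),
                   p1 = rep("A", 4), p2 = rep("G", 4))
  out <- mark_poly(tab)
  expect_equal(out$flag_poly, c("fail", "pass", "fail", "fail"))
  expect_equal(out$reason[out$marker == "allN"], "poly:no_data")
})

test_that("mendelian chi-square matches the worked values and stats::chisq.test", {
  perfect <- mendelian_chi2(c(n_p1p1 = 25, n_het = 50, n_p2p2 = 25),
                            cross_type("F2"))
  expect_equal(perfect$statistic, 0)
  expect_equal(perfect$p_value, 1)

  f2 <- mendelian_chi2(c(n_p1p1 = 40, n_het = 40, n_p2p2 = 20),
                       cross_type("F2"))
  expect_equal(f2$statistic, 12.0)
  expect_equal(f2$dof, 2)
  # independent oracle
  ref <- suppressWarnings(stats::chisq.test(c(40, 40, 20),
                                            p = c(0.25, 0.5, 0.25)))
  expect_equal(f2$statistic, unname(ref$statistic))
  expect_equal(f2$p_value, unname(ref$p.value))

  n2 <- mendelian_chi2(c(n_p1p1 = 60, n_het = 40, n_p2p2 = 0),
                       cross_type("N2", recurrent = "p1"))
  expect_equal(n2$statistic, 4.0)
  ref2 <- suppressWarnings(stats::chisq.test(c(60, 40), p = c(0.5, 0.5)))
  expect_equal(n2$p_value, unname(ref2$p.value))

  expect_error(mendelian_chi2(c(n_p1p1 = 0, n_het = 0, n_p2p2 = 0),
                              cross_type("F2")), "informative")
})

test_that("mark_prop proportion mode enforces minimum class proportions", {
  make_counts <- function(nAA, nAB, nBB) {
    c(rep("A", nAA), rep("H", nAB), rep("G", nBB))
  }
  tab <- toy_table(list(lowhomo = make_counts(5, 55, 40),
                        mendel = make_counts(25, 50, 25),
                        lowhet = make_counts(40, 5, 55)),
                   p1 = rep("A", 3), p2 = rep("G", 3))
  out <- mark_prop(tab, cross_type("F2"), filter_config())
  expect_equal(out$flag_prop, c("fail", "pass", "fail"))
  expect_equal(out$reason[3], "prop:class_below_minimum")
})

test_that("mark_prop chi-square mode uses the configured alpha", {
  calls <- c(rep("A", 40), rep("H", 40), rep("G", 20))  # chi2 = 12, p ~ 0.0025
  tab <- toy_table(list(m = calls), p1 = "A", p2 = "G")
  expect_equal(mark_prop(tab, cross_type("F2"),
                         filter_config(prop_mode = "chi2"))$flag_prop, "fail")
  expect_equal(mark_prop(tab, cross_type("F2"),
                         filter_config(prop_mode = "chi2",
                                       chi2_alpha = 0.001))$flag_prop, "pass")
})

test_that("X markers are tested on homozygote classes only; Y/M are bypassed", {
  # 45% A, 45% H, 10% G would pass autosomal defaults but the G-homozygote
  # class sits below 10% once hets are excluded from nothing -- on X only the
  # two homozygote classes are read, 4/49 < 10%
  callsX <- c(rep("A", 45), rep("H", 51), rep("G", 4))
  ann <- toy_ann(c("mx", "my"), chr = c("X", "Y"), cM = c(1, 1))
  geno <- toy_geno(list(mx = callsX, my = c(rep("A", 90), rep("G", 10))))
  tab <- build_marker_table(geno, ann,
                            toy_parents(c("mx", "my"), c("A", "A"), c("G", "G")))
  out <- mark_prop(tab, cross_type("F2"), filter_config())
  expect_equal(out$flag_prop[out$marker == "mx"], "fail")
  expect_equal(out$reason[out$marker == "mx"], "prop:x_homozygote_deficit")
  expect_equal(out$flag_prop[out$marker == "my"], "pass")  # bypassed
})

test_that("filters are idempotent and order-invariant", {
  pp <- sim_with_parents(sim_config(n_individuals = 50,
                                    map = sim_map(2, 15, 2), seed = 23,
                                    error_spec = c(random_call = 2,
                                                   high_missing = 2,
                                                   nonpolymorphic = 2)))
  cfg <- filter_config(prop_mode = "chi2")
  cross <- cross_type("F2")
  tab <- build_marker_table(pp$sim$geno, pp$sim$map, pp$parents)
  tab <- mark_allele(tab, cross, cfg)

  once <- mark_na(tab, cfg)
  twice <- mark_na(once, cfg)
  expect_identical(once$flag_na, twice$flag_na)
  expect_identical(mark_poly(mark_poly(tab))$flag_poly, mark_poly(tab)$flag_poly)
  expect_identical(mark_allele(mark_allele(tab, cross, cfg), cross, cfg)$flag_allele,
                   mark_allele(tab, cross, cfg)$flag_allele)

  # na/poly/prop read only the counts: their flags commute
  abc <- mark_prop(mark_poly(mark_na(tab, cfg)), cross, cfg)
  cba <- mark_na(mark_poly(mark_prop(tab, cross, cfg)), cfg)
  for (f in c("flag_na", "flag_poly", "flag_prop")) {
    expect_identical(abc[[f]], cba[[f]])
  }
})

test_that("the pipeline log shrinks monotonically and matches the export", {
  pp <- sim_with_parents(sim_config(n_individuals = 60,
                                    map = sim_map(3, 15, 2), seed = 29,
                                    error_spec = c(random_call = 2,
                                                   parent_monomorphic_sgipoly = 2)))
  res <- run_pipeline(pp$sim$geno, pp$sim$map, pp$parents, cross_type("F2"),
                      filter_config(prop_mode = "chi2"))
  expect_true(all(diff(res$log$n_out) <= 0))
  expect_true(all(res$log$n_out == res$log$n_in - res$log$n_excluded))
  expect_equal(res$log$n_out[nrow(res$log)], ncol(res$encoded$geno))

  # the parent-monomorphic markers are gone from the encoded cross
  bad <- pp$sim$truth$labels$marker[
    pp$sim$truth$labels$class == "parent_monomorphic_sgipoly"]
  expect_false(any(bad %in% colnames(res$encoded$geno)))
})

test_that("filter configuration round-trips through YAML with defaults intact", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("na_max: 0.3", "prop_mode: chi2", "parNH_strict: true"), path)
  cfg <- filter_config_from_yaml(path)
  expect_equal(cfg$na_max, 0.3)
  expect_equal(cfg$prop_mode, "chi2")
  expect_true(cfg$parNH_strict)
  expect_equal(cfg$chi2_alpha, 0.05)  # untouched default

  writeLines("not_a_field: 1", path)
  expect_error(filter_config_from_yaml(path), "unknown field")
})
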