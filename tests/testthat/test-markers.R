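# stats table helper for screening tests
statsTable <- function(id, contig, pos, pic, maf = 0.3, missing = 0) {
  S4Vectors::DataFrame(id = id, contig = contig, pos = pos, maf = maf,
                       pic = pic, missing_rate = missing)
}

test_that("candidate screening filters, ranks and spaces markers", {
  st <- statsTable(paste0("m", 1:5), rep("c1", 5),
                   c(1000, 5000, 9000, 13000, 17000),
                   pic = c(0.37, 0.35, 0.33, 0.31, 0.30))
  # high missing rate excluded
  st$missing_rate <- c(0.2, 0, 0, 0, 0)
  got <- screenCandidates(st, criteria = candidateScreenCriteria(
    target_count = 3, min_spacing = 1000))
  expect_equal(got, c("m2", "m3", "m4"))
  # two markers 10 bp apart with spacing 1000: the lower-PIC one is dropped
  st2 <- statsTable(c("a", "b", "c"), rep("c1", 3), c(1000, 1010, 9000),
                    pic = c(0.37, 0.30, 0.33))
  got2 <- suppressWarnings(screenCandidates(st2,
    criteria = candidateScreenCriteria(target_count = 3, min_spacing = 1000)))
  expect_setequal(got2, c("a", "c"))
  expect_false("b" %in% got2)
  # 5 passing markers, target 3: the 3 with highest PIC, deterministic order
  st3 <- statsTable(paste0("x", 1:5), rep("c1", 5),
                    c(1, 3000, 6000, 9000, 12000) + 1000,
                    pic = c(0.31, 0.36, 0.30, 0.373, 0.34))
  got3 <- screenCandidates(st3, criteria = candidateScreenCriteria(
    target_count = 3, min_spacing = 1000))
  expect_equal(got3, c("x4", "x2", "x5"))
  # PIC fallback: preferred floor 0.30 yields too few, fallback 0.20 kicks in
  st4 <- statsTable(paste0("y", 1:4), rep("c1", 4),
                    c(1000, 5000, 9000, 13000),
                    pic = c(0.35, 0.25, 0.22, 0.15))
  got4 <- screenCandidates(st4, criteria = candidateScreenCriteria(
    target_count = 3, min_spacing = 1000))
  expect_equal(got4, c("y1", "y2", "y3"))
  # too few survivors even after the fallback: return all, with a warning
  expect_warning(
    got4b <- screenCandidates(st4, criteria = candidateScreenCriteria(
      target_count = 4, min_spacing = 1000)), "3 candidate")
  expect_equal(got4b, c("y1", "y2", "y3"))
  # MAF floor
  st5 <- statsTable(c("z1", "z2"), "c1", c(1000, 5000), pic = c(0.35, 0.35),
                    maf = c(0.1, 0.3))
  got5 <- suppressWarnings(screenCandidates(st5,
    criteria = candidateScreenCriteria(target_count = 2)))
  expect_equal(got5, "z2")
})

test_that("screening honors design status and region class", {
  st <- statsTable(c("m1", "m2", "m3"), "c1", c(1000, 5000, 9000),
                   pic = rep(0.35, 3))
  regions <- factor(c("exonic_cds", "intronic", "exonic_cds"))
  panel <- data.frame(marker_id = c("m1", "m2", "m3"),
                      status = c("designed", "designed", "failed(x)"))
  got <- suppressWarnings(screenCandidates(st, regions, panel,
    candidateScreenCriteria(target_count = 3)))
  expect_equal(got, "m1")
})

test_that("identification efficiency counts resolved pairs", {
  g <- makeGt(matrix(c("AA", "AA", "GG", "GG"), 1), ref = "A", alt = "G")
  expect_equal(identificationEfficiency(g, lociIds(g)), 4 / 6)
  expect_equal(identificationEfficiency(g, character(0)), 0)
  g2 <- makeGt(rbind(c("AA", "AG", "GG"), c("AA", "AA", "AG")),
               ref = c("A", "A"), alt = c("G", "G"))
  expect_equal(identificationEfficiency(g2, lociIds(g2)), 1.0)
  # a missing call never distinguishes
  g3 <- makeGt(matrix(c("AA", NA), 1), ref = "A", alt = "G")
  expect_equal(identificationEfficiency(g3, lociIds(g3)), 0)
})

test_that("greedy core-marker selection matches the toy brute force", {
  # S1..S4; M1 = [A,A,G,G], M2 = [A,G,A,G], M3 = [A,A,A,G] (hom calls)
  g <- makeGt(rbind(c("AA", "AA", "GG", "GG"),
                    c("AA", "GG", "AA", "GG"),
                    c("AA", "AA", "AA", "GG")),
              ref = rep("A", 3), alt = rep("G", 3),
              pos = c(1000, 2000, 3000))
  sel <- selectCoreMarkers(g, lociIds(g))
  expect_setequal(sel$core_markers, lociIds(g)[1:2])
  expect_equal(sel$efficiency, 1.0)
  expect_equal(nrow(sel$unresolved_pairs), 0L)
  # exhaustive search over all 7 subsets confirms 2 is the minimum
  gmat <- t(kaspanel:::alleleCodes(g)$a1 * 4L +
            kaspanel:::alleleCodes(g)$a2)
  bf <- bruteMarkerCover(gmat)
  expect_equal(bf$max_covered, bf$n_pairs)
  expect_equal(bf$min_size, 2L)
  # saturation curve is non-decreasing and ends at the all-candidate efficiency
  expect_true(all(diff(sel$saturation$efficiency) >= 0))
  expect_equal(tail(sel$saturation$efficiency, 1),
               identificationEfficiency(g, lociIds(g)))
})

test_that("duplicate accessions plateau below full efficiency", {
  g <- makeGt(rbind(c("AA", "AG", "GG", "GG"),
                    c("AA", "GG", "AG", "AG")),
              ref = c("A", "A"), alt = c("G", "G"))
  sel <- selectCoreMarkers(g, lociIds(g))
  expect_lt(sel$efficiency, 1.0)
  expect_equal(nrow(sel$unresolved_pairs), 1L)
  expect_setequal(unlist(sel$unresolved_pairs[1, ]), c("S03", "S04"))
})

test_that("a genotype-identical candidate is never selected", {
  g <- makeGt(rbind(c("AA", "AA", "GG", "GG"),
                    c("AA", "AA", "GG", "GG"),   # identical column pattern
                    c("AA", "GG", "AA", "GG")),
              ref = rep("A", 3), alt = rep("G", 3),
              pos = c(1000, 2000, 3000))
  sel <- selectCoreMarkers(g, lociIds(g))
  expect_length(intersect(sel$core_markers, lociIds(g)[1:2]), 1L)
})

test_that("greedy + prune is superset-minimal and near-optimal on random instances", {
  set.seed(77)
  for (k in 1:40) {
    n_acc <- sample(4:8, 1); n_mk <- sample(3:10, 1)
    gm <- matrix(sample(c(0L, 1L, 2L, NA), n_acc * n_mk, replace = TRUE,
                        prob = c(.4, .3, .25, .05)), n_acc, n_mk)
    geno <- matrix(c("AA", "AG", "GG")[gm + 1L], n_acc, n_mk)
    g <- makeGt(t(geno), ref = rep("A", n_mk), alt = rep("G", n_mk),
                pos = seq(1000, by = 1000, length.out = n_mk))
    sel <- selectCoreMarkers(g, lociIds(g))
    bf <- bruteMarkerCover(gm)
    # same achieved coverage as the exhaustive optimum
    expect_equal(sel$efficiency, bf$max_covered / bf$n_pairs)
    # within +1 of the optimum cardinality (greedy set-cover bound at this scale)
    expect_lte(length(sel$core_markers), bf$min_size + 1L)
    # superset-minimal: removing any selected marker lowers efficiency
    for (m in sel$core_markers) {
      rest <- setdiff(sel$core_markers, m)
      eff <- identificationEfficiency(g, rest)
      expect_lt(eff, sel$efficiency)
    }
  }
})

test_that("fingerprint codes and uniqueness reporting", {
  g <- makeGt(rbind(c("CC", "CT", NA), c("TT", "TG", "GG")),
              ref = c("C", "T"), alt = c("T", "G"),
              pos = c(1000, 2000))
  fp <- buildFingerprint(g, lociIds(g))
  expect_equal(unname(fp$table[1, ]), c("C/C", "T/T"))
  expect_equal(unname(fp$table[2, ]), c("C/T", "G/T"))
  expect_equal(unname(fp$table[3, ]), c("./.", "G/G"))
  expect_equal(unname(fp$classes[1, ]), c("hom", "hom"))
  expect_equal(unname(fp$classes[2, 1]), "het")
  expect_equal(unname(fp$classes[3, 1]), "missing")
  expect_error(buildFingerprint(g, character(0)), "empty")
  # all rows unique <=> efficiency 1
  expect_equal(fp$efficiency, 1.0)
  expect_equal(nrow(fp$indistinguishable_pairs), 0L)
  g2 <- makeGt(matrix(c("AA", "AA", "GG"), 1), ref = "A", alt = "G")
  fp2 <- buildFingerprint(g2, lociIds(g2))
  expect_lt(fp2$efficiency, 1)
  expect_equal(nrow(fp2$indistinguishable_pairs), 1L)
})
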