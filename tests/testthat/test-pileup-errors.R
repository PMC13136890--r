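# Enumerated pileup rows with hand-computed total variation percentages.
tv_cases <- list(
  list(ref = "A", a = 100,                               exp = 0),
  list(ref = "A", del = 50,                              exp = 100),
  list(ref = "A", a = 70, g = 10, del = 15, ins = 5,     exp = 30),
  list(ref = "C", c = 90, a = 10,                        exp = 10),
  list(ref = "U", u = 50, del = 50,                      exp = 50),
  list(ref = "G", g = 25, a = 25, c = 25, u = 25,        exp = 75),
  list(ref = "A", a = 1,                                 exp = 0),
  list(ref = "A", g = 1,                                 exp = 100),
  list(ref = "U", u = 99, ins = 1,                       exp = 1),
  list(ref = "C", c = 80, del = 10, ins = 10,            exp = 20),
  list(ref = "G", g = 60, u = 20, del = 10, ins = 10,    exp = 40),
  list(ref = "A", a = 199, c = 1,                        exp = 0.5),
  list(ref = "U", u = 75, a = 5, c = 5, g = 5, del = 5, ins = 5, exp = 25),
  list(ref = "C", ins = 10,                              exp = 100),
  list(ref = "A", a = 30, del = 30, ins = 40,            exp = 70),
  list(ref = "G", g = 997, a = 1, c = 1, u = 1,          exp = 0.3),
  list(ref = "U", u = 40, g = 40,                        exp = 50),
  list(ref = "A", a = 64, g = 16, del = 16, ins = 4,     exp = 36),
  list(ref = "C", c = 45, u = 45, del = 9, ins = 1,      exp = 55),
  list(ref = "G", g = 9, a = 1,                          exp = 10),
  list(ref = "A", a = 120, del = 40, ins = 40,           exp = 40),
  list(ref = "U", u = 1, del = 1, ins = 2,               exp = 75)
)

make_row <- function(cs) {
  pileup_row(cs$ref,
             a = cs$a %||% 0, c = cs$c %||% 0, g = cs$g %||% 0,
             u = cs$u %||% 0, del = cs$del %||% 0, ins = cs$ins %||% 0)
}

test_that("total variation matches hand-computed values exactly", {
  for (i in seq_along(tv_cases)) {
    row <- make_row(tv_cases[[i]])
    expect_identical(total_variation(row), tv_cases[[i]]$exp,
                     label = sprintf("case %d", i))
  }
})

test_that("zero-denominator positions are undefined, not 0%", {
  row <- pileup_row("A")
  expect_true(is.na(total_variation(row)))
  bd <- error_breakdown(row)
  expect_true(is.na(bd$total_variation_pct))
})

test_that("breakdown components share the denominator and sum to the total", {
  for (i in seq_along(tv_cases)) {
    row <- make_row(tv_cases[[i]])
    bd <- error_breakdown(row)
    comp <- bd$mismatch_a + bd$mismatch_c + bd$mismatch_g + bd$mismatch_u +
      bd$deletion_frac + bd$insertion_frac
    expect_equal(comp, bd$total_variation_pct / 100, tolerance = 1e-12,
                 label = sprintf("case %d", i))
  }
  # named example: ref A, a=70, g=10, del=15, ins=5
  bd <- error_breakdown(make_row(tv_cases[[3]]))
  expect_equal(bd$mismatch_g, 0.10)
  expect_equal(bd$deletion_frac, 0.15)
  expect_equal(bd$insertion_frac, 0.05)
  expect_equal(bd$mismatch_a, 0)  # reference base never counts as mismatch
})

test_that("breakdown sum rule holds across a whole simulated table", {
  sim <- simulate_dataset(tiny_sim_config(seed = 3))
  for (pt in sim$pileup) {
    bd <- error_breakdown(pt)
    comp <- rowSums(bd[, c("mismatch_a", "mismatch_c", "mismatch_g",
                           "mismatch_u", "deletion_frac",
                           "insertion_frac")])
    ok <- !is.na(bd$total_variation_pct)
    expect_true(all(abs(comp[ok] - bd$total_variation_pct[ok] / 100) < 1e-9))
    tv <- total_variation(pt)
    expect_true(all(tv[!is.na(tv)] >= 0 & tv[!is.na(tv)] <= 100))
  }
})

test_that("error_delta subtracts per position and propagates NA", {
  ctrl <- pileup_table(data.frame(
    position = 1:3, ref_base = "A",
    a = c(95, 0, 100), c = c(5, 0, 0), g = 0, u = 0,
    del_calls = 0, ins_calls = 0))
  mod <- pileup_table(data.frame(
    position = 1:3, ref_base = "A",
    a = c(75, 50, 100), c = c(25, 0, 0), g = 0, u = 0,
    del_calls = 0, ins_calls = 0))
  d <- error_delta(mod, ctrl)
  expect_equal(d$delta[1], 20)          # 25% - 5%
  expect_true(is.na(d$delta[2]))        # control undefined at position 2
  expect_equal(d$delta[3], 0)           # identical rows
  expect_equal(error_delta(mod, mod)$delta, rep(0, 3))
  shifted <- pileup_table(data.frame(
    position = 11:13, ref_base = "A", a = 1, c = 0, g = 0, u = 0,
    del_calls = 0, ins_calls = 0))
  expect_error(error_delta(mod, shifted), "disjoint")
})

test_that("simulated modified sites carry higher error than background", {
  sim <- simulate_dataset(sim_config(seed = 17))
  tv <- total_variation(sim$pileup$modified)
  sites <- sim$truth$position
  p <- wilcox.test(tv[sites], tv[setdiff(seq_along(tv), sites)],
                   alternative = "greater", exact = FALSE)$p.value
  expect_lt(p, 0.01)
  expect_lt(median(tv[setdiff(seq_along(tv), sites)], na.rm = TRUE),
            median(tv[sites], na.rm = TRUE))
})

test_that("alignment pileups equal hand-enumerated counts on toy fixtures", {
  skip_if_not_installed("Rsamtools")
  skip_if_not_installed("GenomicAlignments")
  ref <- "ACGTACGTAC"
  sam <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:ref\tLN:10",
    "r1\t0\tref\t1\t60\t10M\t*\t0\t0\tACGTACGTAC\t*",
    "r2\t0\tref\t1\t60\t4M1D5M\t*\t0\t0\tACGTCGTAC\t*",
    "r3\t0\tref\t1\t60\t5M2I5M\t*\t0\t0\tACGTAGGCGTAC\t*",
    "r4\t0\tref\t1\t10\t10M\t*\t0\t0\tACGTACGTAC\t*",
    "r5\t256\tref\t1\t60\t10M\t*\t0\t0\tACGTACGTAC\t*")
  dir <- withr::local_tempdir()
  sam_path <- file.path(dir, "toy.sam")
  writeLines(sam, sam_path)
  bam <- Rsamtools::asBam(sam_path, file.path(dir, "toy"),
                          overwrite = TRUE, indexDestination = TRUE)
  pt <- pileup_from_alignments(bam, ref, min_mapq = 20)

  # r4 (mapq 10) and r5 (secondary) are excluded: depth 3 everywhere
  expect_equal(pt$depth, rep(3L, 10))
  # r2's deletion sits at reference position 5
  expect_equal(pt$del_calls, c(0, 0, 0, 0, 1, 0, 0, 0, 0, 0))
  # r3's 2-nt insertion counts once, anchored at the position it follows
  expect_equal(pt$ins_calls, c(0, 0, 0, 0, 1, 0, 0, 0, 0, 0))
  # reference alphabet normalized to RNA
  expect_equal(pt$ref_base, strsplit("ACGUACGUAC", "")[[1]])
  expect_equal(total_variation(pt),
               c(0, 0, 0, 0, 50, 0, 0, 0, 0, 0))

  # perfect reads only: zero variation at every position
  sam2 <- c(sam[1:2], vapply(c("p1", "p2", "p3"), function(id) {
    sprintf("%s\t0\tref\t1\t60\t10M\t*\t0\t0\tACGTACGTAC\t*", id)
  }, character(1)))
  sam2_path <- file.path(dir, "perfect.sam")
  writeLines(sam2, sam2_path)
  bam2 <- Rsamtools::asBam(sam2_path, file.path(dir, "perfect"),
                           overwrite = TRUE, indexDestination = TRUE)
  pt2 <- pileup_from_alignments(bam2, ref)
  expect_equal(pt2$depth, rep(3L, 10))
  expect_equal(total_variation(pt2), rep(0, 10))

  # a missing index is an I/O error
  file.remove(paste0(bam, ".bai"))
  expect_error(pileup_from_alignments(bam, ref), "index")
})
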