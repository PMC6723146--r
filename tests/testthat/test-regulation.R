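test_that("signed ratio and gene-specific cut-off follow their closed forms", {
  expect_equal(signed_fold_change(20, 10), 2)
  expect_equal(signed_fold_change(5, 10), -2)
  expect_equal(signed_fold_change(10, 10), 1)
  expect_error(signed_fold_change(0, 10), "positive")

  expect_equal(cut_threshold(0, 0), 1)
  expect_equal(cut_threshold(0.1, 0.1), 1.2)
  expect_equal(cut_threshold(0.3, 0.4), 1.707107, tolerance = 1e-6)
  expect_error(cut_threshold(-0.1, 0.1), "non-negative")

  # |x| and CUT invariant to swapping conditions; sign tracks the difference
  expect_equal(abs(signed_fold_change(4, 12)), abs(signed_fold_change(12, 4)))
  expect_equal(cut_threshold(0.2, 0.5), cut_threshold(0.5, 0.2))
  expect_equal(sign(signed_fold_change(4, 12)), -1)
})

test_that("Welch p matches stats::t.test and handles degenerate groups", {
  expect_equal(welch_p(c(1, 2, 3, 4), c(1, 2, 3, 4)), 1)
  expect_lt(welch_p(c(1, 1.001, 0.999, 1), c(2, 2.001, 1.999, 2)), 0.01)
  set.seed(42)
  for (i in 1:20) {
    a <- stats::rnorm(4, 10, 2)
    b <- stats::rnorm(4, 11, 1)
    expect_equal(welch_p(a, b), stats::t.test(a, b)$p.value,
                 tolerance = 1e-9)
  }
  # one constant group still follows the Welch formula
  a <- c(5, 5, 5, 5); b <- c(6, 7, 5, 8)
  expect_equal(welch_p(a, b), stats::t.test(a, b)$p.value, tolerance = 1e-9)
  # both constant: equal means -> 1, different means -> 0
  expect_equal(welch_p(c(2, 2, 2, 2), c(2, 2, 2, 2)), 1)
  expect_equal(welch_p(c(2, 2, 2, 2), c(3, 3, 3, 3)), 0)
  expect_error(welch_p(1, c(1, 2)), "at least 2")
})

test_that("regulation calls are by |x| > CUT alone", {
  cfg <- synthetic_config(n_genes = 60L, seed = 13, planted = NULL)
  pair <- generate_paired_conditions(cfg, regulated_fraction = 0.3,
                                     effect_law = function(n) rep(4, n))
  a <- normalize_median(as_filtered(pair$a))
  b <- normalize_median(as_filtered(pair$b))
  al <- align_conditions(b, a)
  sc <- res_per_gene(rev_per_gene(al[[1]]))
  sn <- res_per_gene(rev_per_gene(al[[2]]))
  rc <- regulation_calls(sc, sn, al[[1]], al[[2]])
  expect_true(all(abs(rc$x) >= 1))
  expect_true(all(rc$CUT >= 1))
  expect_true(all(rc$p >= 0 & rc$p <= 1))
  expect_identical(rc$call == "up", rc$x >= 0 & abs(rc$x) > rc$CUT)
  expect_identical(rc$call == "down", rc$x < 0 & abs(rc$x) > rc$CUT)
  # a universe mismatch is refused
  sub <- gmrank:::restrict_genes(a, names(a$gene_index)[1:30])
  expect_error(regulation_calls(sc, res_per_gene(rev_per_gene(sub)),
                                al[[1]], sub), "unaligned")
})

test_that("duplicated input gives x = 1, p = 1 and WPR exactly 0", {
  d <- normalize_median(as_filtered(random_probe_dataset(12, seed = 21)))
  s <- res_per_gene(rev_per_gene(d))
  rc <- regulation_calls(s, s, d, d)
  expect_true(all(rc$x == 1))
  expect_true(all(rc$p == 1))
  expect_true(all(rc$call == "not_significant"))
  mu <- stats::setNames(s$genes$mu, s$genes$gene_id)
  expect_equal(as.numeric(wpr(rc, mu, rc$gene_id)), 0)
})

test_that("WPR weights magnitude, confidence and normal-condition level", {
  rec <- data.frame(gene_id = c("A", "B"), x = c(2, -1.5),
                    CUT = c(1.2, 1.2), p = c(0.01, 0.5),
                    call = c("up", "not_significant"),
                    stringsAsFactors = FALSE)
  mu <- c(A = 1, B = 2)
  expect_equal(as.numeric(wpr(rec, mu, c("A", "B"))),
               (1 * 1 * 0.99 + 2 * 0.5 * 0.5) / 2)  # = 0.745
  expect_equal(attr(wpr(rec, mu, c("A", "B")), "n_members"), 2)

  # unchanged genes (x = +/-1) and p = 1 members contribute nothing
  rec0 <- data.frame(gene_id = c("A", "B"), x = c(1, -1), CUT = 1,
                     p = c(0.2, 0.9), call = "not_significant")
  expect_equal(as.numeric(wpr(rec0, mu, c("A", "B"))), 0)
  rec1 <- data.frame(gene_id = "A", x = 3, CUT = 1, p = 1, call = "up")
  expect_equal(as.numeric(wpr(rec1, mu, "A")), 0)

  # literal |x - 1| variant scores an unchanged down-direction gene as 2
  expect_equal(as.numeric(wpr(rec0, mu, c("A", "B"), literal_eq4 = TRUE)),
               (1 * 0 * 0.8 + 2 * 2 * 0.1) / 2)

  # GCH weighting variant
  expect_equal(as.numeric(wpr(rec, mu, c("A", "B"), weight = "gch",
                              gch = c(A = 10, B = 1))),
               (10 * 1 * 0.99 + 1 * 0.5 * 0.5) / 2)
  expect_error(wpr(rec, mu, "missing"), "no quantified members")
})

test_that("WPR is permutation-invariant and monotone in |x|", {
  rec <- data.frame(gene_id = letters[1:4], x = c(2, -3, 1.2, -1.6),
                    CUT = 1.2, p = c(0.1, 0.2, 0.9, 0.4),
                    call = "up", stringsAsFactors = FALSE)
  mu <- stats::setNames(rep(1, 4), letters[1:4])
  w1 <- as.numeric(wpr(rec, mu, letters[1:4]))
  w2 <- as.numeric(wpr(rec[sample(4), ], mu, letters[4:1]))
  expect_equal(w1, w2)
  rec$x[2] <- -5
  expect_gt(as.numeric(wpr(rec, mu, letters[1:4])), w1)
})
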