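fake_inputs <- function(rev, cp, res = log(median(rev) / rev),
                        genes = sprintf("g%d", seq_along(rev))) {
  list(summary = structure(list(genes = data.frame(gene_id = genes, REV = rev,
                                                   RES = res, mu = 1),
                                median_rev = stats::median(rev)),
                           class = "DatasetSummary"),
       profile = structure(list(cp = stats::setNames(cp, genes),
                                mean_cp = mean(cp), n_genes = length(cp)),
                           class = "CoordinationProfile"))
}

test_that("GCH evaluates its closed forms", {
  fi <- fake_inputs(rev = c(1, 1, 0.5), cp = c(0, 1, 0.5))
  g <- gch_scores(fi$summary, fi$profile)
  expect_equal(g$GCH[1], 1)                      # neutral gene
  expect_equal(g$GCH[2], exp(4), tolerance = 1e-12)   # ceiling ~ 54.598
  expect_equal(g$GCH[3], 2 * exp(2), tolerance = 1e-12)
  expect_equal(attr(g, "form"), "approx4")

  ge <- gch_scores(fi$summary, fi$profile, form = "exact_ratio")
  expect_equal(ge$GCH,
               exp(fi$summary$genes$RES + fi$profile$cp / fi$profile$mean_cp),
               ignore_attr = TRUE)

  bad <- fake_inputs(rev = c(1, 1), cp = c(0, 0), genes = c("a", "b"))
  bad$profile$cp <- stats::setNames(c(0, 0), c("a", "zz"))
  expect_error(gch_scores(bad$summary, bad$profile), "universe mismatch")
})

test_that("GCH is monotone in stability and coordination in both forms", {
  for (form in c("approx4", "exact_ratio")) {
    fi <- fake_inputs(rev = c(0.1, 0.2, 0.4, 0.8), cp = rep(0.3, 4))
    g <- gch_scores(fi$summary, fi$profile, form = form)
    expect_true(all(diff(g$GCH) < 0))
    fi <- fake_inputs(rev = rep(0.3, 4), cp = c(0.1, 0.2, 0.3, 0.4))
    g <- gch_scores(fi$summary, fi$profile, form = form)
    expect_true(all(diff(g$GCH) > 0))
  }
})

test_that("ranking is deterministic with alphabetical ties", {
  tab <- data.frame(gene_id = c("c", "a", "b"), GCH = c(5, 9, 1),
                    rank = NA_integer_)
  rk <- rank_genes(tab)
  expect_equal(rk$gene_id, c("a", "c", "b"))
  expect_equal(rk$rank[match(c("c", "a", "b"), rk$gene_id)], c(2L, 1L, 3L))

  tie <- data.frame(gene_id = c("zz", "aa"), GCH = c(3, 3), rank = NA_integer_)
  expect_equal(rank_genes(tie)$gene_id, c("aa", "zz"))

  perm <- rank_genes(tab[c(2, 3, 1), ])
  expect_identical(perm, rk)
  expect_error(rank_genes(tab[0, ]), "empty")
})

test_that("GMR actionability reflects the top-two GCH gap", {
  mk <- function(g1, g2) data.frame(gene_id = c("top", "second"),
                                    GCH = c(g1, g2), rank = 1:2)
  call <- gmr_call(mk(82.95, 48.40))          # reported MET-region gap
  expect_equal(call$gap_ratio, 82.95 / 48.40, tolerance = 1e-12)
  expect_equal(round(call$gap_ratio, 3), 1.714)
  expect_true(call$actionable)
  call2 <- gmr_call(mk(173.58, 39.11))        # far-above hierarchy
  expect_equal(round(call2$gap_ratio, 3), 4.438)
  expect_true(call2$actionable)
  expect_false(gmr_call(mk(10, 10))$actionable)
  expect_equal(gmr_call(mk(10, 10))$gap_ratio, 1)
  expect_error(gmr_call(mk(1, 1)[1, ]), "at least 2")
})

test_that("cross-condition tables carry top genes across conditions", {
  t1 <- rank_genes(data.frame(gene_id = c("a", "b", "c", "d"),
                              GCH = c(9, 7, 5, 3), rank = NA_integer_))
  t2 <- rank_genes(data.frame(gene_id = c("b", "c", "d", "e"),
                              GCH = c(10, 2, 8, 6), rank = NA_integer_))
  tab <- cross_condition_table(list(one = t1, two = t2), k = 3)
  expect_lte(nrow(tab), 6)
  expect_setequal(names(tab), c("gene_id", "lead_condition", "one", "two"))
  expect_true(is.na(tab$two[tab$gene_id == "a"]))   # unquantified -> N/A
  expect_equal(tab$one[tab$gene_id == "b"], 7)
  expect_equal(tab$two[tab$gene_id == "b"], 10)

  dup <- cross_condition_table(list(x = t1, y = t1), k = 3)
  expect_equal(dup$x, dup$y)
  t3 <- rank_genes(data.frame(gene_id = c("q", "r"), GCH = c(1, 2),
                              rank = NA_integer_))
  expect_error(cross_condition_table(list(a = t1, b = t3)), "no gene overlap")
})

test_that("concordance compares GCH and perturbation-consequence orderings", {
  expect_equal(concordance_report(c(g = 10), c(g = 2),
                                  c(g = 0.9), c(g = 0.1))$fraction, 1)
  expect_equal(concordance_report(c(g = 10), c(g = 2),
                                  c(g = 0.1), c(g = 0.9))$fraction, 0)
  # the four-gene crossed design: two genes higher in each line
  ga <- c(n = 30, p = 25, d = 5, u = 4)
  gb <- c(n = 6, p = 7, d = 40, u = 33)
  wa <- c(n = 3, p = 2.5, d = 0.2, u = 0.1)
  wb <- c(n = 0.4, p = 0.3, d = 4, u = 3)
  out <- concordance_report(ga, gb, wa, wb)
  expect_equal(out$fraction, 1)
  expect_true(all(out$table$concordant))
  expect_error(concordance_report(ga, gb[1:3], wa, wb), "mismatch")
})

test_that("approx4 ranking equals ranking by RES + 4 CP", {
  set.seed(5)
  rev <- stats::runif(15, 0.05, 0.6)
  cp <- stats::runif(15, 0, 0.6)
  fi <- fake_inputs(rev = rev, cp = cp)
  rk <- rank_genes(gch_scores(fi$summary, fi$profile))
  byscore <- fi$summary$genes$gene_id[order(-(fi$summary$genes$RES + 4 * cp),
                                            fi$summary$genes$gene_id)]
  expect_equal(rk$gene_id, byscore)
})
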