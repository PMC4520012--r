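test_that("the FNR is the undetected fraction among expressed testers", {
  testers <- tibble::tibble(expressed = c(TRUE, TRUE, TRUE, TRUE, FALSE),
                            detected_sexlinked = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  f <- estimate_fnr(testers)
  expect_equal(f$fnr, 0.25)
  expect_equal(f$n_expressed, 4)
  expect_equal(f$prop_expressed, 0.8)
  all_det <- tibble::tibble(expressed = TRUE, detected_sexlinked = TRUE)
  expect_equal(estimate_fnr(all_det)$fnr, 0)
  expect_error(estimate_fnr(tibble::tibble(expressed = FALSE,
                                           detected_sexlinked = FALSE)),
               "expressed tester")
})

test_that("undetected genes partition into missed pairs and hemizygotes, conserving the total", {
  expect_equal(unlist(correct_counts(22, 0.25, 43)), c(10.75, 11.25),
               ignore_attr = TRUE)
  expect_equal(unlist(correct_counts(4, 0.25, 7)), c(1.75, 2.25),
               ignore_attr = TRUE)
  expect_equal(unlist(correct_counts(9, 0, 40)), c(0, 9), ignore_attr = TRUE)
  # conservation over random inputs
  withr::with_seed(4, {
    for (rep in 1:25) {
      E <- sample(5:100, 1); U <- sample(0:E, 1); f <- runif(1, 0, U / E)
      cc <- correct_counts(U, f, E)
      expect_equal(cc$expected_xy_undetected + cc$undetected_hemi, U)
    }
  })
  expect_warning(cc <- correct_counts(2, 0.5, 10), "clipped")
  expect_equal(cc$undetected_hemi, 0)
  expect_error(correct_counts(10, 0.2, 5), "exceed")
})

test_that("loss proportions divide total hemizygotes by the ancestral count", {
  expect_equal(loss_proportion(5, 11.25, 50), 33)   # 16.25/50 = 32.5
  expect_equal(loss_proportion(5, 11.25, 60), 27)
  expect_equal(loss_proportion(1, 2.25, 50, n_hemi_excluded = 1), 5)
  expect_equal(loss_proportion(1, 2.25, 60, n_hemi_excluded = 1), 4)
  expect_error(loss_proportion(1, 1, 0), "n_ancestral")
  # f = 0 reduces to the naive detected-plus-undetected estimate
  E <- 40; U <- 12; H <- 6
  cc0 <- correct_counts(U, 0, E)
  expect_equal(loss_proportion(H, cc0$undetected_hemi, 50, rounded = FALSE),
               100 * (H + U) / 50)
  # f = U/E zeroes the undetected remainder
  ccU <- correct_counts(U, U / E, E)
  expect_equal(ccU$undetected_hemi, 0)
})

test_that("loss proportion is nonincreasing in the FNR and nondecreasing in U", {
  E <- 43; A <- 50; H <- 5
  fs <- seq(0, 0.5, by = 0.05)
  by_f <- sapply(fs, function(f) {
    cc <- suppressWarnings(correct_counts(22, f, E))
    loss_proportion(H, cc$undetected_hemi, A, rounded = FALSE)
  })
  expect_true(all(diff(by_f) <= 0))
  us <- 0:30
  by_u <- sapply(us, function(u) {
    cc <- suppressWarnings(correct_counts(u, 0.25, E))
    loss_proportion(H, cc$undetected_hemi, A, rounded = FALSE)
  })
  expect_true(all(diff(by_u) >= 0))
})

test_that("the Fisher contrast equals hypergeometric enumeration", {
  same <- contrast_xy_loss(5, 20, 5, 20)
  expect_equal(same$p_value, 1.0)
  got <- contrast_xy_loss(16, 50, 2, 50)
  expect_equal(got$p_value, fisher_enum_p(16, 34, 2, 48), tolerance = 1e-12)
  expect_equal(got$y_lost, 16)
  # fractional corrected counts are rounded half-up before testing
  frac <- contrast_xy_loss(16.25, 50, 2.25, 50)
  expect_equal(frac$p_value, got$p_value)
  expect_error(contrast_xy_loss(5, 0, 1, 10), "totals")
})

test_that("expression comparison matches the textbook pooled t-tail", {
  ident <- compare_expression(c(5, 6, 7), c(5, 6, 7))
  expect_equal(ident$p_value, 0.5)
  got <- compare_expression(c(10, 20, 30), c(1, 2, 3))
  expect_equal(got$p_value, t_pooled_oracle(c(1, 2, 3), c(10, 20, 30)),
               tolerance = 1e-10)
  expect_equal(got$mean_detected, 20)
  expect_equal(got$mean_undetected, 2)
  # degenerate group: means reported, p absent
  tiny <- compare_expression(c(5), c(1, 2))
  expect_true(is.na(tiny$p_value))
  expect_equal(tiny$mean_detected, 5)
  expect_error(compare_expression(numeric(), 1), "non-empty")
})

test_that("the end-to-end estimate reproduces the corrected bookkeeping", {
  fx <- silene_bac_fixture()
  combined <- classify_genes(fx$genes, fx$matches, fx$calls)
  est <- estimate_loss(combined, fx$genes, testers = fx$testers)
  td <- tidy(est)
  x <- td[td$linkage == "X", ]
  expect_equal(x$expected_xy_undetected, 10.75)
  expect_equal(x$undetected_hemi, 11.25)
  expect_equal(x$total_hemi, 16.25)
  expect_equal(c(x$loss_pct, x$loss_pct_incl_probes), c(33, 27))
  y <- td[td$linkage == "Y", ]
  expect_equal(y$expected_xy_undetected, 1.75)
  expect_equal(y$total_hemi, 2.25)       # anomalous detected call dropped
  expect_equal(c(y$loss_pct, y$loss_pct_incl_probes), c(5, 4))
  g <- glance(est)
  expect_equal(g$n_ancestral, 50)
  expect_equal(g$n_ancestral_incl_probes, 60)
  expect_lt(g$fisher_p, 1e-3)
  # keeping the anomalous call moves the Y side to 3.25
  est_keep <- estimate_loss(combined, fx$genes, testers = fx$testers,
                            exclude_anomalous = FALSE)
  expect_equal(tidy(est_keep)$total_hemi[2], 3.25)
})

test_that("restricting to outgroup-anchored genes behaves like a subset analysis", {
  fx <- silene_bac_fixture()
  combined <- classify_genes(fx$genes, fx$matches, fx$calls)
  # subset = full set leaves the estimate unchanged
  all_genes <- fx$genes
  all_genes$has_outgroup_homolog[all_genes$species == "latifolia"] <- TRUE
  full <- estimate_loss(combined, all_genes, testers = fx$testers)
  sub <- restrict_to_outgroup(combined, all_genes, testers = fx$testers)
  expect_equal(tidy(sub), tidy(full))
  # genes gained by the X (no outgroup homolog) that are all hemizygous
  # inflate the unrestricted estimate relative to the restricted one
  gained <- tiny_genes(sprintf("gn%d", 1:6))
  gained$has_outgroup_homolog <- FALSE
  genes2 <- dplyr::bind_rows(all_genes, gained)
  m2 <- tibble::tibble(gene_id = gained$gene_id, study_id = "M2012",
                       contig_id = paste0("M2012_h_", gained$gene_id))
  c2 <- tibble::tibble(study_id = "M2012", contig_id = m2$contig_id,
                       label = "X_HEMI")
  combined2 <- classify_genes(genes2, dplyr::bind_rows(fx$matches, m2),
                              dplyr::bind_rows(fx$calls, c2))
  unrestricted <- estimate_loss(combined2, genes2, testers = fx$testers)
  restricted <- restrict_to_outgroup(combined2, genes2, testers = fx$testers)
  expect_lt(tidy(restricted)$loss_prop[1], tidy(unrestricted)$loss_prop[1])
  # exact cancellation: H = 0 and U = f*E gives 0 % loss
  cc <- correct_counts(10, 0.25, 40)
  expect_equal(loss_proportion(0, cc$undetected_hemi, 50), 0)
})

test_that("tidy, glance and autoplot expose the fitted object", {
  fx <- silene_bac_fixture()
  combined <- classify_genes(fx$genes, fx$matches, fx$calls)
  est <- estimate_loss(combined, fx$genes, testers = fx$testers)
  expect_s3_class(tidy(est), "tbl_df")
  expect_equal(nrow(glance(est)), 1)
  p <- autoplot(est)
  expect_s3_class(p, "ggplot")
})
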