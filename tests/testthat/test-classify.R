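make_matches <- function(labels, gene = "g1") {
  tibble::tibble(
    gene_id = gene,
    study_id = sprintf("st%d", seq_along(labels)),
    contig_id = sprintf("st%d_c%d", seq_along(labels), seq_along(labels))
  )
}
make_calls <- function(labels) {
  tibble::tibble(
    study_id = sprintf("st%d", seq_along(labels)),
    contig_id = sprintf("st%d_c%d", seq_along(labels), seq_along(labels)),
    label = labels
  )
}

test_that("category precedence is XY > X_HEMI > UNDETECTED over any label multiset", {
  labels <- c("XY", "X_HEMI", "NOT_SEX_LINKED")
  combos <- expand.grid(a = labels, b = labels, c = labels,
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    ls <- unlist(combos[i, ])
    expected <- if (any(ls == "XY")) "XY"
                else if (any(ls == "X_HEMI")) "X_HEMI"
                else "UNDETECTED"
    got <- combine_calls(make_matches(ls), make_calls(ls))
    expect_equal(got$category, expected, info = paste(ls, collapse = ","))
    expect_true(got$expressed)
  }
})

test_that("combination is invariant under permutation and duplication of matches", {
  withr::with_seed(5, {
    for (rep in 1:20) {
      ls <- sample(c("XY", "X_HEMI", "NOT_SEX_LINKED"),
                   sample(1:5, 1), replace = TRUE)
      m <- make_matches(ls); calls <- make_calls(ls)
      base <- combine_calls(m, calls)
      perm <- combine_calls(m[sample(nrow(m)), ], calls)
      dupl <- combine_calls(m[c(seq_len(nrow(m)), 1), ], calls)
      expect_equal(perm, base)
      expect_equal(dupl, base)
    }
  })
})

test_that("genes without matches are NO_MATCH and unresolvable contigs degrade gracefully", {
  genes <- tiny_genes(c("gx1", "gx2"), "gy1")
  matches <- tibble::tibble(gene_id = c("gx1", "gy1"),
                            study_id = c("st1", "st1"),
                            contig_id = c("st1_c1", "st1_missing"))
  calls <- tibble::tibble(study_id = "st1", contig_id = "st1_c1", label = "XY")
  expect_warning(
    combined <- classify_genes(genes, matches, calls),
    "NOT_SEX_LINKED")
  expect_equal(combined$category[combined$gene_id == "gx1"], "XY")
  # unresolvable contig counts as a not-sex-linked match, not a crash
  expect_equal(combined$category[combined$gene_id == "gy1"], "UNDETECTED")
  expect_equal(combined$category[combined$gene_id == "gx2"], "NO_MATCH")
  expect_false(combined$expressed[combined$gene_id == "gx2"])
  # unknown gene id in matches is an error
  bad <- matches; bad$gene_id[1] <- "nope"
  expect_error(classify_genes(genes, bad, calls), "unknown gene_id")
})

test_that("a Y-linked gene combined as X-hemizygous is flagged anomalous", {
  genes <- tiny_genes("gx1", "gy1")
  matches <- tibble::tibble(gene_id = c("gx1", "gy1"),
                            study_id = "st1",
                            contig_id = c("st1_c1", "st1_c2"))
  calls <- tibble::tibble(study_id = "st1",
                          contig_id = c("st1_c1", "st1_c2"),
                          label = "X_HEMI")
  combined <- classify_genes(genes, matches, calls)
  expect_equal(combined$anomalous, c(FALSE, TRUE))
  expect_equal(unique(combined$category), "X_HEMI")
})

test_that("tabulation reproduces the packaged per-category counts", {
  fx <- silene_bac_fixture()
  combined <- classify_genes(fx$genes, fx$matches, fx$calls)
  tab <- tabulate_categories(combined, fx$genes, probes = "exclude")
  x <- tab[tab$linkage == "X", ]
  expect_equal(unlist(x[c("n_total", "n_no_match", "n_retained",
                          "n_xy", "n_hemi", "n_undetected")], use.names = FALSE),
               c(49, 6, 43, 16, 5, 22))
  y <- tab[tab$linkage == "Y", ]
  expect_equal(unlist(y[c("n_total", "n_no_match", "n_retained",
                          "n_xy", "n_hemi", "n_undetected")], use.names = FALSE),
               c(10, 3, 7, 2, 1, 4))
  expect_equal(y$n_anomalous_hemi, 1L)

  # comparison set: new genes plus single-copy probes, 54 of 63 matched
  cmp <- tabulate_categories(combined, fx$genes, probes = "single_copy")
  expect_equal(sum(cmp$n_total), 63)
  expect_equal(sum(cmp$n_retained), 54)

  # conservation holds in every mode
  for (mode in c("exclude", "single_copy", "include")) {
    t <- tabulate_categories(combined, fx$genes, probes = mode)
    expect_equal(t$n_xy + t$n_hemi + t$n_undetected, t$n_retained)
    expect_equal(t$n_retained + t$n_no_match, t$n_total)
  }
})

test_that("empty call sets tabulate to all-NO_MATCH, and XY counts are monotone in upgrades", {
  genes <- tiny_genes(c("gx1", "gx2"), "gy1")
  combined <- classify_genes(genes, make_matches(character()),
                             make_calls(character()))
  tab <- tabulate_categories(combined, genes)
  expect_equal(sum(tab$n_retained), 0)
  expect_equal(sum(tab$n_no_match), 3)

  # upgrading any NOT_SEX_LINKED label to XY never decreases the XY count
  withr::with_seed(9, {
    for (rep in 1:10) {
      n <- 6
      matches <- tibble::tibble(gene_id = sprintf("g%d", sample(1:3, n, TRUE)),
                                study_id = "st1",
                                contig_id = sprintf("st1_c%d", 1:n))
      calls <- tibble::tibble(study_id = "st1",
                              contig_id = sprintf("st1_c%d", 1:n),
                              label = sample(c("XY", "X_HEMI", "NOT_SEX_LINKED"),
                                             n, TRUE))
      g <- tiny_genes(sprintf("g%d", 1:3))
      before <- classify_genes(g, matches, calls)
      nsl <- which(calls$label == "NOT_SEX_LINKED")
      if (length(nsl) == 0) next
      calls$label[sample(nsl, 1)] <- "XY"
      after <- classify_genes(g, matches, calls)
      expect_gte(sum(after$category == "XY"), sum(before$category == "XY"))
    }
  })
})
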