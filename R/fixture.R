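#' Packaged BAC-study reproduction fixture
#'
#' In-memory transcription of the published per-gene bookkeeping: 153
#' gene records (58 X-linked, 17 Y-linked, 78 outgroup), the combined
#' RNA-seq match/call structure that yields the published per-category
#' counts (X side: 16 X/Y, 5 X-hemizygous, 22 undetected, 6 without
#' matches among 49 new genes; Y side: 2/1/4/3 among 10), and the
#' 70-gene tester set with 56 expressed testers of which 14 were not
#' ascertained sex-linked (false-negative rate exactly 0.25).
#'
#' Per-gene identities and RPKM values are not published; identifiers
#' are systematic placeholders and the RPKM column is synthetic (fixed,
#' deterministic values with the detected group more highly expressed).
#' Counts, categories, probe structure and tester totals are the
#' published ones.
#'
#' @return A list with tibbles `genes`, `matches`, `calls`, `testers`.
#' @export
silene_bac_fixture <- function() {
  # --- new X-linked genes: 16 XY, 5 X_HEMI, 22 UNDETECTED, 6 NO_MATCH ---
  x_new <- tibble(
    gene_id = sprintf("SlX%03d", 1:49),
    species = "latifolia", linkage = "X",
    is_probe = FALSE, is_new = TRUE,
    bac_id = sprintf("bacX%02d", 1 + (0:48) %% 10),
    has_outgroup_homolog = sprintf("SlX%03d", 1:49) %in%
      sprintf("SlX%03d", c(1:4, 17:18, 22:26, 45:46)),
    probe_family = NA_character_
  )
  x_cat <- c(rep("XY", 16), rep("X_HEMI", 5), rep("UNDETECTED", 22),
             rep("NO_MATCH", 6))

  # --- new Y-linked genes: 2 XY, 1 X_HEMI (anomalous), 4 UNDETECTED, 3 NO_MATCH
  y_new <- tibble(
    gene_id = sprintf("SlY%03d", 1:10),
    species = "latifolia", linkage = "Y",
    is_probe = FALSE, is_new = TRUE,
    bac_id = sprintf("bacY%02d", 1 + (0:9) %% 8),
    has_outgroup_homolog = sprintf("SlY%03d", 1:10) %in% c("SlY001", "SlY004"),
    probe_family = NA_character_
  )
  y_cat <- c(rep("XY", 2), "X_HEMI", rep("UNDETECTED", 4), rep("NO_MATCH", 3))

  # --- probe genes: families F01-F06 with both copies, F07-F09 X-only,
  #     F10 Y-only; 10 families, 9 X + 7 Y entries ---
  x_probe <- tibble(
    gene_id = sprintf("SlXp%02d", 1:9),
    species = "latifolia", linkage = "X",
    is_probe = TRUE, is_new = FALSE,
    bac_id = sprintf("bacX%02d", 1 + (0:8) %% 10),
    has_outgroup_homolog = TRUE,
    probe_family = sprintf("F%02d", 1:9)
  )
  y_probe <- tibble(
    gene_id = sprintf("SlYp%02d", c(1:6, 10)),
    species = "latifolia", linkage = "Y",
    is_probe = TRUE, is_new = FALSE,
    bac_id = sprintf("bacY%02d", 1 + (0:6) %% 8),
    has_outgroup_homolog = TRUE,
    probe_family = sprintf("F%02d", c(1:6, 10))
  )

  # --- outgroup genes: 70 new + 8 probe homologs, no sex linkage ---
  v_genes <- bind_rows(
    tibble(gene_id = sprintf("Sv%03d", 1:70),
           species = "vulgaris", linkage = "unknown",
           is_probe = FALSE, is_new = TRUE,
           bac_id = sprintf("bacV%02d", 1 + (0:69) %% 8),
           has_outgroup_homolog = NA, probe_family = NA_character_),
    tibble(gene_id = sprintf("Svp%02d", 1:8),
           species = "vulgaris", linkage = "unknown",
           is_probe = TRUE, is_new = FALSE,
           bac_id = sprintf("bacV%02d", 1 + (0:7) %% 8),
           has_outgroup_homolog = NA,
           probe_family = sprintf("F%02d", 1:8))
  )

  genes <- bind_rows(x_new, y_new, x_probe, y_probe, v_genes)

  # synthetic RPKM (per-gene values unpublished): ascertained genes are
  # more highly expressed than unascertained ones
  cat_all <- stats::setNames(c(x_cat, y_cat, rep("XY", nrow(x_probe) +
                                                   nrow(y_probe))),
                             c(x_new$gene_id, y_new$gene_id,
                               x_probe$gene_id, y_probe$gene_id))
  genes$rpkm <- NA_real_
  det_x <- x_new$gene_id[x_cat %in% c("XY", "X_HEMI")]
  und_x <- x_new$gene_id[x_cat == "UNDETECTED"]
  genes$rpkm[match(det_x, genes$gene_id)] <- 1000 * seq_along(det_x)
  genes$rpkm[match(und_x, genes$gene_id)] <- 250 * seq_along(und_x)

  # --- matches and per-study calls realising the categories ---
  studies <- c("M2012", "BC2011", "CF2011")
  rows <- list()
  add <- function(gene, study, contig, label) {
    rows[[length(rows) + 1]] <<- tibble(gene_id = gene, study_id = study,
                                        contig_id = contig, label = label)
  }
  focal_ids <- names(cat_all)
  for (i in seq_along(focal_ids)) {
    g <- focal_ids[i]
    cat_g <- cat_all[[g]]
    st <- studies[1 + (i - 1) %% 3]
    cid <- function(s, tag = "c") sprintf("%s_%s_%s", s, tag, g)
    if (cat_g == "NO_MATCH") next
    if (cat_g == "XY") {
      if (g %in% c("SlX015", "SlX016")) {
        # X-hemizygous in one study but X/Y in another: combined as X/Y
        add(g, "CF2011", cid("CF2011"), "X_HEMI")
        add(g, "BC2011", cid("BC2011"), "XY")
      } else {
        add(g, st, cid(st), "XY")
      }
    } else if (cat_g == "X_HEMI") {
      add(g, st, cid(st), "X_HEMI")
      st2 <- studies[1 + (i %% 3)]
      add(g, st2, cid(st2), "NOT_SEX_LINKED")
    } else { # UNDETECTED
      add(g, st, cid(st), "NOT_SEX_LINKED")
    }
  }
  tabs <- bind_rows(rows)
  matches <- select(tabs, "gene_id", "study_id", "contig_id")
  calls <- distinct(select(tabs, "study_id", "contig_id", "label"))

  # --- tester set: 70 validated X/Y pairs, 56 expressed, 14 undetected ---
  prov <- rep(c("experimental", "pcr_validated", "segregation", "radseq"),
              times = c(17, 20, 12, 21))
  unexpressed <- c(1:3, 18:21, 38:40, 50:53)        # 14 testers
  undetected <- c(4:6, 22:25, 41:42, 54:58)         # 14 expressed, missed
  testers <- tibble(
    gene_id = sprintf("tester%02d", 1:70),
    expressed = !(1:70 %in% unexpressed),
    detected_sexlinked = !(1:70 %in% c(unexpressed, undetected)),
    provenance = prov
  )

  list(genes = validate_gene_table(genes), matches = matches,
       calls = calls, testers = testers)
}

#' Write the packaged fixture as TSV files
#'
#' Emits `genes.tsv`, `matches.tsv`, `calls.tsv` and `testers.tsv` in the
#' dialects the readers expect — convenient for exercising the
#' command-line interface on real files.
#'
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_fixture_tables <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fx <- silene_bac_fixture()
  readr::write_tsv(fx$genes, file.path(dir, "genes.tsv"))
  readr::write_tsv(fx$matches, file.path(dir, "matches.tsv"))
  readr::write_tsv(fx$calls, file.path(dir, "calls.tsv"))
  readr::write_tsv(fx$testers, file.path(dir, "testers.tsv"))
  invisible(dir)
}

#' Run the full analysis on the packaged fixture
#'
#' End-to-end reproduction: gene densities and size-expected ratios, the
#' combined classification and its tabulation, the FNR-corrected loss
#' estimates with and without probe genes, the X-vs-Y Fisher contrast,
#' the outgroup-restricted re-analysis and the expression comparison.
#'
#' @param method Correction mode for [estimate_loss()] (default
#'   `"paper"`, the table-reproduction arithmetic).
#' @return A report bundle (class `ydegen_report`) serialisable with
#'   [write_report()].
#' @export
reproduce_bac_study <- function(method = "paper") {
  fx <- silene_bac_fixture()
  dens <- density_report(fx$genes)
  combined <- classify_genes(fx$genes, fx$matches, fx$calls)
  tab_new <- tabulate_categories(combined, fx$genes, probes = "exclude")
  tab_cmp <- tabulate_categories(combined, fx$genes, probes = "single_copy")
  est <- estimate_loss(combined, fx$genes, testers = fx$testers,
                       method = method)
  est_outgroup <- restrict_to_outgroup(combined, fx$genes,
                                       testers = fx$testers, method = method)
  det <- combined$gene_id[combined$category %in% c("XY", "X_HEMI")]
  und <- combined$gene_id[combined$category == "UNDETECTED"]
  rpkm <- stats::setNames(fx$genes$rpkm, fx$genes$gene_id)
  expr_cmp <- compare_expression(
    rpkm[det][!is.na(rpkm[det])], rpkm[und][!is.na(rpkm[und])])
  bundle <- list(
    densities = dens$densities,
    density_ratios = dens$ratios,
    loss_from_density_pct = dens$loss_from_density_pct,
    tabulation_new_genes = tab_new,
    n_genes_compared = sum(tab_cmp$n_total),
    n_genes_matched = sum(tab_cmp$n_retained),
    fnr = est$fnr,
    loss = tidy(est),
    loss_summary = glance(est),
    loss_outgroup_summary = glance(est_outgroup),
    expression_comparison = expr_cmp
  )
  class(bundle) <- c("ydegen_report", "list")
  bundle
}
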