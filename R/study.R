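# End-to-end study: simulate -> segment -> extract -> compare, plus the
# reporting surface (print/summary/plot/export of the comparison report).

#' Reproducibility analysis of a study feature matrix
#'
#' Computes per-feature ICCs for every observer set (manual inter-observer,
#' the two semi-auto inter-observer run sets, the per-observer intra run
#' pairs), classification counts, rank-sum comparisons between groups and
#' the Z-normalized range statistics.
#'
#' @param features study feature data frame ([extract_study_features()] or
#'   [read_feature_matrix()]).
#' @param range_mode passed to [znormalize_and_range()].
#' @return a `radrobust_report` object.
#' @export
analyze_features <- function(features, range_mode = "per_tumor") {
  sets <- observer_sets(features)
  icc_tables <- lapply(names(sets), function(nm) {
    icc_per_feature(features, sets[[nm]]$columns,
                    model = if (sets[[nm]]$model == "twoway") "twoway" else "oneway")
  })
  names(icc_tables) <- names(sets)

  inter_sa <- grep("^semiauto_set", names(icc_tables), value = TRUE)
  intra <- grep("^intra_o", names(icc_tables), value = TRUE)

  # per-feature semi-auto inter-observer ICC, averaged over the run sets
  sa_avg <- icc_tables[[inter_sa[1]]][, c("feature", "icc")]
  if (length(inter_sa) > 1) {
    for (nm in inter_sa[-1]) sa_avg$icc <- sa_avg$icc + icc_tables[[nm]]$icc
    sa_avg$icc <- sa_avg$icc / length(inter_sa)
  }
  sa_avg$class <- as.character(classify_icc(sa_avg$icc))
  man <- icc_tables$manual

  intra_avg <- NULL
  if (length(intra)) {
    intra_avg <- icc_tables[[intra[1]]][, c("feature", "icc")]
    if (length(intra) > 1) {
      for (nm in intra[-1]) intra_avg$icc <- intra_avg$icc + icc_tables[[nm]]$icc
      intra_avg$icc <- intra_avg$icc / length(intra)
    }
  }

  fam <- feature_families()
  test_by <- function(sel) {
    wilcoxon_ranksum(man$icc[sel], sa_avg$icc[sel])
  }
  all_sel <- rep(TRUE, nrow(man))
  tests <- list(
    all = test_by(all_sel),
    intensity = test_by(fam[man$feature] == "intensity"),
    shape = test_by(fam[man$feature] == "shape"),
    texture = test_by(fam[man$feature] == "texture"))

  class_counts <- function(cls) {
    tab <- table(factor(cls, levels = c("high", "medium", "low", "unclassified")))
    as.list(tab)
  }

  report <- list(
    features = features,
    icc_tables = icc_tables,
    manual = man,
    semiauto_avg = sa_avg,
    intra_avg = intra_avg,
    summaries = list(
      manual = summarize_icc(man),
      semiauto = summarize_icc(sa_avg),
      intra = if (!is.null(intra_avg)) summarize_icc(intra_avg) else NULL),
    tests = tests,
    n_features = nrow(man),
    n_higher_semiauto = sum(sa_avg$icc > man$icc, na.rm = TRUE),
    class_counts = list(manual = class_counts(man$class),
                        semiauto = class_counts(sa_avg$class)),
    range_stats = znormalize_and_range(features, mode = range_mode),
    provenance = list(package_version = as.character(utils::packageVersion("radrobust")),
                      n_tumors = length(unique(features$tumor)),
                      generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  structure(report, class = "radrobust_report")
}

#' Run the complete synthetic reproducibility study
#'
#' Generates the phantom cohort and all observer segmentations, extracts the
#' 56-feature panel for every segmentation and runs the reproducibility
#' analysis. When `out_dir` is given, all intermediates (volumes, masks,
#' manifest, feature CSV) and the report summary are persisted so every
#' stage can be re-run and every reported number recomputed.
#'
#' @param config a [study_config()].
#' @param out_dir optional directory for persisted intermediates.
#' @param bin_width discretization bin width (HU).
#' @param format image format for persisted volumes (`"nrrd"`/`"nifti"`).
#' @param verbose report per-stage progress.
#' @return a `radrobust_report` (with the dataset attached as
#'   `attr(, "dataset")`).
#' @export
run_study <- function(config = study_config(), out_dir = NULL,
                      bin_width = 25, format = "nrrd", verbose = FALSE) {
  ds <- generate_study(config, out_dir = out_dir, format = format,
                       verbose = verbose)
  feats <- extract_study_features(ds, bin_width = bin_width)
  if (!is.null(out_dir))
    write_feature_matrix(feats, file.path(out_dir, "features.csv"),
                         params = list(bin_width = bin_width, distance = 1,
                                       connectivity = 26, area_mode = "mesh",
                                       master_seed = config$master_seed))
  rep_ <- analyze_features(feats)
  rep_$provenance$master_seed <- config$master_seed
  if (!is.null(out_dir)) export_report(rep_, out_dir)
  attr(rep_, "dataset") <- ds
  rep_
}

#' @export
print.radrobust_report <- function(x, ...) {
  sm <- x$summaries
  cat("<radrobust_report>\n")
  cat(sprintf("  %d features x %d tumors, %d segmentations/tumor\n",
              x$n_features, x$provenance$n_tumors,
              sum(x$features$tumor == x$features$tumor[1])))
  cat(sprintf("  inter-observer ICC: manual %.2f+/-%.2f, semi-auto %.2f+/-%.2f (p = %.3g)\n",
              sm$manual$mean[1], sm$manual$sd[1],
              sm$semiauto$mean[1], sm$semiauto$sd[1], x$tests$all$p_value))
  if (!is.null(sm$intra))
    cat(sprintf("  intra-observer ICC (semi-auto): %.2f+/-%.2f\n",
                sm$intra$mean[1], sm$intra$sd[1]))
  cat(sprintf("  features with higher semi-auto ICC: %d/%d\n",
              x$n_higher_semiauto, x$n_features))
  cat(sprintf("  normalized range p = %.3g (lower %.3g, upper %.3g)\n",
              x$range_stats$tests$range$p_value,
              x$range_stats$tests$lower$p_value,
              x$range_stats$tests$upper$p_value))
  invisible(x)
}

#' @export
summary.radrobust_report <- function(object, ...) {
  print(object)
  cat("\nICC mean +/- SD by family:\n")
  for (g in c("manual", "semiauto", "intra")) {
    s <- object$summaries[[g]]
    if (is.null(s)) next
    cat(sprintf("  %-9s %s\n", g, paste(
      sprintf("%s %.2f+/-%.2f", s$set, s$mean, s$sd), collapse = " | ")))
  }
  cat("\nReproducibility classes (counts):\n")
  for (g in c("manual", "semiauto")) {
    cc <- object$class_counts[[g]]
    cat(sprintf("  %-9s high %d, medium %d, low %d, unclassified %d\n", g,
                cc$high, cc$medium, cc$low, cc$unclassified))
  }
  invisible(object)
}

#' Plot a reproducibility report
#'
#' @param x a `radrobust_report`.
#' @param which `"boxplot"` (ICC distributions per observer set),
#'   `"families"` (per-family mean ICC bars) or `"range"` (normalized range
#'   per feature and group).
#' @param ... passed to the underlying base-graphics call.
#' @export
plot.radrobust_report <- function(x, which = c("boxplot", "families", "range"),
                                  ...) {
  which <- match.arg(which)
  if (which == "boxplot") {
    sets <- c(list(manual = x$manual$icc),
              lapply(x$icc_tables[grep("^semiauto_set", names(x$icc_tables))],
                     function(t) t$icc),
              lapply(x$icc_tables[grep("^intra_o", names(x$icc_tables))],
                     function(t) t$icc))
    graphics::boxplot(sets, ylab = "ICC", las = 2,
                      col = c("tomato", rep("skyblue", 2), rep("palegreen", 3)),
                      main = "Inter- and intra-observer feature reproducibility",
                      ...)
  } else if (which == "families") {
    fam <- feature_families()
    mm <- sapply(c("intensity", "shape", "texture"), function(f) c(
      manual = mean(x$manual$icc[fam[x$manual$feature] == f], na.rm = TRUE),
      semiauto = mean(x$semiauto_avg$icc[fam[x$semiauto_avg$feature] == f],
                      na.rm = TRUE)))
    graphics::barplot(mm, beside = TRUE, ylim = c(0, 1), ylab = "mean ICC",
                      legend.text = rownames(mm),
                      main = "Feature-family reproducibility", ...)
  } else {
    pf <- x$range_stats$per_feature
    man <- pf$range[pf$group == "manual"]
    sa <- pf$range[pf$group == "semiauto"]
    o <- order(man)
    graphics::matplot(cbind(man[o], sa[o]), type = "l", lty = 1,
                      col = c("tomato", "skyblue"),
                      xlab = "feature (sorted)", ylab = "normalized range",
                      main = "Z-normalized feature range across observers", ...)
    graphics::legend("topleft", c("manual", "semi-auto"), lty = 1,
                     col = c("tomato", "skyblue"), bty = "n")
  }
  invisible(x)
}

#' Export a report to CSV + JSON
#'
#' Writes `icc_table.csv` (per feature: manual ICC and class, semi-auto
#' averaged ICC and class), one CSV per observer set, and `report.json`
#' with the summaries, tests, classification counts, range statistics and
#' provenance. Re-export is idempotent.
#'
#' @param report a `radrobust_report`.
#' @param out_dir output directory (created if needed).
#' @export
export_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  tab <- data.frame(feature = report$manual$feature,
                    manual_icc = report$manual$icc,
                    manual_class = report$manual$class,
                    semiauto_icc = report$semiauto_avg$icc,
                    semiauto_class = report$semiauto_avg$class,
                    stringsAsFactors = FALSE)
  write.csv(tab, file.path(out_dir, "icc_table.csv"), row.names = FALSE)
  for (nm in names(report$icc_tables))
    write.csv(report$icc_tables[[nm]],
              file.path(out_dir, sprintf("icc_%s.csv", nm)), row.names = FALSE)
  js <- list(summaries = report$summaries,
             tests = lapply(report$tests, function(t) t["p_value"]),
             n_higher_semiauto = report$n_higher_semiauto,
             n_features = report$n_features,
             class_counts = report$class_counts,
             range_tests = lapply(report$range_stats$tests, function(t) t["p_value"]),
             range_mode = report$range_stats$mode,
             provenance = report$provenance)
  jsonlite::write_json(js, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(out_dir)
}
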