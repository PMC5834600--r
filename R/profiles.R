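#' Profile-level summaries and reporting
#'
#' Sample x marker percent-positive matrices, PCA and hierarchical
#' clustering of the expression profiles, and figure/report rendering.
#'
#' @name profiles
NULL

#' Build a sample x marker percent-positive matrix
#'
#' Rows are samples (population x donor), columns markers, values percent
#' positive on the 0-100 scale. Missing values are imputed with the marker
#' (column) mean; a fully missing marker is imputed as 0.
#'
#' @param result `screen_result` (or its `percent_positive` long table)
#' @param subset "all" (default), "positive" or "enriched" marker subset;
#'   subsets other than "all" require the `screen_result`
#' @return numeric matrix with a `subset` attribute
#' @export
profile_matrix <- function(result, subset = c("all", "positive",
                                              "enriched")) {
  subset <- match.arg(subset)
  long <- if (inherits(result, "screen_result"))
    result$percent_positive else result
  keep <- unique(long$marker)
  if (subset != "all") {
    if (!inherits(result, "screen_result"))
      stop("marker subsets require a screen_result")
    keep <- result$markers$marker[result$markers[[subset]]]
  }
  long <- long[long$marker %in% keep, ]
  sample_id <- paste(long$population, long$donor, sep = "_")
  m <- tapply(long$pct_positive, list(sample_id, long$marker), mean)
  m <- m[, intersect(keep, colnames(m)), drop = FALSE]
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    if (anyNA(col)) {
      fill <- if (all(is.na(col))) 0 else mean(col, na.rm = TRUE)
      m[is.na(col), j] <- fill
    }
  }
  attr(m, "subset") <- subset
  m
}

#' PCA of expression profiles
#'
#' Column-centered (optionally unit-scaled) principal component analysis of
#' the percent-positive matrix. Explained-variance fractions are
#' non-increasing and sum to at most 1.
#'
#' @param m sample x marker matrix (see [profile_matrix()])
#' @param n_components number of components to return (default all)
#' @param scale. unit-variance scaling (default FALSE; raw percentages)
#' @return list: `scores`, `explained_variance` (fractions), `rotation`,
#'   `center`
#' @export
pca_profiles <- function(m, n_components = NULL, scale. = FALSE) {
  if (nrow(m) < 2) stop("PCA requires >= 2 samples")
  vars <- apply(m, 2, stats::var)
  if (all(vars == 0)) {
    warning("zero-variance matrix: all scores are zero")
    k <- min(n_components %||% 1L, nrow(m) - 1L)
    return(list(scores = matrix(0, nrow(m), k,
                                dimnames = list(rownames(m),
                                                paste0("PC", seq_len(k)))),
                explained_variance = rep(0, k),
                rotation = NULL, center = colMeans(m)))
  }
  if (scale. && any(vars == 0))
    m <- m[, vars > 0, drop = FALSE]
  p <- stats::prcomp(m, center = TRUE, scale. = scale.)
  ev <- p$sdev^2 / sum(p$sdev^2)
  k <- min(n_components %||% length(ev), length(ev))
  list(scores = p$x[, seq_len(k), drop = FALSE],
       explained_variance = ev[seq_len(k)],
       rotation = p$rotation[, seq_len(k), drop = FALSE],
       center = p$center)
}

#' Hierarchical clustering of samples and markers
#'
#' Agglomerative clustering (Euclidean distance, average linkage by
#' default) of the profile matrix rows (samples) and columns (markers).
#' The top split of the sample tree is reported as a two-group membership
#' vector.
#'
#' @param m sample x marker matrix
#' @param method linkage passed to [stats::hclust()] (default "average")
#' @return list: `samples`, `markers` (hclust objects; `markers` is NULL
#'   for a single-column matrix), `sample_order`, `marker_order`,
#'   `top_split` (named integer vector of 1/2)
#' @export
hcluster_profiles <- function(m, method = "average") {
  if (nrow(m) < 2) stop("clustering requires >= 2 samples")
  hs <- stats::hclust(stats::dist(m), method = method)
  hm <- if (ncol(m) >= 2)
    stats::hclust(stats::dist(t(m)), method = method) else NULL
  list(samples = hs, markers = hm,
       sample_order = rownames(m)[hs$order],
       marker_order = if (!is.null(hm)) colnames(m)[hm$order]
       else colnames(m),
       top_split = stats::cutree(hs, k = 2))
}

#' Re-simulate and gate selected marker wells to collect reporter vectors
#'
#' Convenience for histogram overlays: for each requested marker, the
#' donor's well is simulated and gated, and the per-population reporter
#' intensities returned.
#'
#' @param config `plate_sim_config`
#' @param markers character vector of marker names
#' @param gate_cfg `gate_config`
#' @param donor donor id (default "D1")
#' @return named list: marker -> list(population -> reporter vector)
#' @export
collect_marker_reporter <- function(config, markers,
                                    gate_cfg = gate_config(),
                                    donor = "D1") {
  lay <- config$layout
  donor_fractions <- draw_donor_fractions(config)
  out <- list()
  for (m in markers) {
    row <- lay[lay$reagent_name == m & lay$reagent_class == "marker", ]
    if (nrow(row) == 0) next
    sim <- simulate_well(config, row$well[1], row$plate[1], donor,
                         donor_fractions = donor_fractions)
    gated <- gate_well(sim$events, gate_cfg)
    out[[m]] <- .pop_reporter(gated, gate_cfg)
  }
  out
}

.fmt <- function(x, digits = 3) formatC(x, format = "f", digits = digits)

#' Render figures and a summary report
#'
#' Writes deterministic-named outputs under `out_dir`: `summary.txt` (flag
#' counts, enriched markers, background ratio), percent-positive heatmaps
#' of the positive and enriched subsets, a PCA scatter plot, a stain-index
#' fold bar chart, and one reporter-histogram overlay per enriched marker
#' when reporter vectors are supplied. Histogram axes use an arcsinh
#' display transform; all statistics remain on the linear scale.
#'
#' @param result `screen_result`
#' @param out_dir output directory
#' @param reporter_by_marker optional output of [collect_marker_reporter()]
#' @param arcsinh_cofactor display cofactor for histograms (default 150)
#' @return character vector of files written, invisibly
#' @export
render_report <- function(result, out_dir, reporter_by_marker = NULL,
                          arcsinh_cofactor = 150) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tab <- result$markers
  files <- character(0)

  enriched <- tab$marker[tab$enriched]
  lines <- c(
    "surface-protein screen summary",
    sprintf("markers analysed: %d", nrow(tab)),
    sprintf("positive (>= threshold in either population): %d",
            sum(tab$positive)),
    sprintf("variable: %d", sum(tab$variable)),
    sprintf("enriched: %d", sum(tab$enriched)),
    if (length(enriched) > 0)
      paste0("enriched markers: ", paste(sort(enriched), collapse = ", "))
    else "enriched markers: none",
    if (!is.null(result$background))
      sprintf("background MFI ratio (%s/%s): %s",
              result$populations[1], result$populations[2],
              .fmt(attr(result$background, "ratio") %||% NA_real_))
  )
  summary_path <- file.path(out_dir, "summary.txt")
  writeLines(lines, summary_path)
  files <- c(files, summary_path)

  for (sub in c("positive", "enriched")) {
    keep <- tab$marker[tab[[sub]]]
    if (length(keep) < 2) next
    m <- profile_matrix(result, subset = sub)
    if (nrow(m) < 2) next
    f <- file.path(out_dir, paste0("heatmap_", sub, ".png"))
    grDevices::png(f, width = 1200, height = 800, res = 120)
    pheatmap::pheatmap(t(m), clustering_method = "average",
                       main = paste(sub, "markers, % positive"))
    grDevices::dev.off()
    files <- c(files, f)
  }

  pm <- profile_matrix(result, subset = "all")
  if (nrow(pm) >= 2 && any(apply(pm, 2, stats::var) > 0)) {
    pca <- pca_profiles(pm, n_components = 2)
    df <- data.frame(PC1 = pca$scores[, 1],
                     PC2 = if (ncol(pca$scores) > 1) pca$scores[, 2] else 0,
                     population = sub("_.*$", "", rownames(pm)))
    g <- ggplot2::ggplot(df, ggplot2::aes(PC1, PC2,
                                          colour = population)) +
      ggplot2::geom_point(size = 3) +
      ggplot2::labs(
        x = sprintf("PC1 (%.1f%%)", 100 * pca$explained_variance[1]),
        y = if (length(pca$explained_variance) > 1)
          sprintf("PC2 (%.1f%%)", 100 * pca$explained_variance[2])
        else "PC2") +
      ggplot2::theme_bw()
    f <- file.path(out_dir, "pca.png")
    ggplot2::ggsave(f, g, width = 6, height = 5, dpi = 120)
    files <- c(files, f)
  }

  if (length(enriched) > 0) {
    sf <- tab[tab$enriched, c("marker", "si_fold")]
    sf <- sf[!is.na(sf$si_fold), ]
    if (nrow(sf) > 0) {
      g <- ggplot2::ggplot(sf, ggplot2::aes(
        stats::reorder(marker, -si_fold), si_fold)) +
        ggplot2::geom_col() +
        ggplot2::geom_hline(yintercept = 1.5, colour = "red") +
        ggplot2::labs(x = NULL, y = "stain-index fold (labelled/reference)") +
        ggplot2::theme_bw() +
        ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                           hjust = 1))
      f <- file.path(out_dir, "si_fold.png")
      ggplot2::ggsave(f, g, width = 6, height = 4, dpi = 120)
      files <- c(files, f)
    }
  }

  if (!is.null(reporter_by_marker)) {
    for (m in intersect(enriched, names(reporter_by_marker))) {
      rp <- reporter_by_marker[[m]]
      df <- do.call(rbind, lapply(names(rp), function(pn)
        data.frame(population = pn,
                   intensity = asinh(rp[[pn]] / arcsinh_cofactor))))
      g <- ggplot2::ggplot(df, ggplot2::aes(intensity,
                                            fill = population)) +
        ggplot2::geom_histogram(alpha = 0.5, bins = 120,
                                position = "identity") +
        ggplot2::labs(title = m, x = "arcsinh reporter intensity") +
        ggplot2::theme_bw()
      f <- file.path(out_dir, paste0("hist_", gsub("[^A-Za-z0-9_-]", "_", m),
                                     ".png"))
      ggplot2::ggsave(f, g, width = 6, height = 4, dpi = 120)
      files <- c(files, f)
    }
  }
  invisible(files)
}
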