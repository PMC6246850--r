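#' Edge-wise two-sample tests between groups
#'
#' For every strictly-upper-triangle edge, a two-sample t-test on the
#' Fisher-z values between two groups of connectomes, with Bonferroni
#' control of the family-wise error over all `R(R-1)/2` edges (diagonal
#' and lower triangle are never tested).  The pooled-variance (classic)
#' t-test is the default; Welch's correction is available by flag.
#' Edges with zero variance in both groups are flagged degenerate and
#' excluded from significance.
#'
#' @param group_a,group_b lists of `functional_connectome` objects (at
#'   least 2 each, shared region order).
#' @param alpha family-wise significance level (default 0.05; the
#'   per-edge threshold is `alpha / n_edges`).
#' @param welch use Welch's unequal-variance t instead of pooled.
#' @return A data.frame of class `edge_test` with one row per edge:
#'   `i`, `j`, `region_i`, `region_j`, `t`, `p`, `significant`,
#'   `degenerate`, plus attributes `alpha`, `n_edges`, `threshold`.
#' @export
edgewise_group_test <- function(group_a, group_b, alpha = 0.05, welch = FALSE) {
  xa <- stack_edges(group_a)
  xb <- stack_edges(group_b)
  if (!identical(attr(xa, "regions"), attr(xb, "regions"))) {
    stop("groups must share one region order", call. = FALSE)
  }
  na <- nrow(xa); nb <- nrow(xb)
  if (na < 2 || nb < 2) stop("need at least 2 subjects per group", call. = FALSE)
  ma <- colMeans(xa); mb <- colMeans(xb)
  va <- apply(xa, 2, stats::var); vb <- apply(xb, 2, stats::var)
  if (welch) {
    se2 <- va / na + vb / nb
    tt <- (ma - mb) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    tt <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(tt))
  }
  degenerate <- (va == 0 & vb == 0)
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  n_edges <- length(tt)
  threshold <- alpha / n_edges
  significant <- !degenerate & is.finite(p) & p < threshold
  regions <- attr(xa, "regions")
  et <- edge_table(length(regions))
  out <- data.frame(i = et$i, j = et$j,
                    region_i = regions[et$i], region_j = regions[et$j],
                    t = tt, p = p, significant = significant,
                    degenerate = degenerate, stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  attr(out, "n_edges") <- n_edges
  attr(out, "threshold") <- threshold
  class(out) <- c("edge_test", "data.frame")
  out
}

# Subjects x edges matrix of row-major upper-triangle values.
stack_edges <- function(group) {
  if (inherits(group, "cohort_data")) group <- group$subjects
  stopifnot(length(group) >= 1)
  ok <- vapply(group, inherits, logical(1), "functional_connectome")
  if (!all(ok)) stop("groups must contain functional_connectome objects", call. = FALSE)
  regions <- group[[1]]$regions
  m <- t(vapply(group, function(s) {
    if (!identical(s$regions, regions)) {
      stop("subjects must share one region order", call. = FALSE)
    }
    upper_tri_vector(s$matrix)
  }, numeric(length(regions) * (length(regions) - 1) / 2)))
  attr(m, "regions") <- regions
  m
}

#' Categorize edges by pre/post stimulation abnormality
#'
#' Crosses the significance maps of two edge-wise group tests — patients
#' vs healthy before stimulation and after stimulation — into four
#' mutually exclusive categories covering every edge:
#' `removed_abnormal` (significant before, not after),
#' `new_abnormal` (not before, significant after),
#' `unchanged_abnormal` (significant in both), and
#' `never_abnormal` (significant in neither).
#'
#' @param pre_test,post_test `edge_test` results over the same edge set.
#' @param parc optional `parcellation` for the lobe-pair summary.
#' @return A list of class `edge_category_map` with `edges` (per-edge
#'   data.frame including `category`) and, when `parc` is given,
#'   `lobe_summary` (category counts per unordered lobe pair).
#' @export
categorize_edges <- function(pre_test, post_test, parc = NULL) {
  if (nrow(pre_test) != nrow(post_test) ||
      !identical(pre_test$i, post_test$i) ||
      !identical(pre_test$j, post_test$j)) {
    stop("pre and post tests must cover the same edge set", call. = FALSE)
  }
  pre_sig <- pre_test$significant
  post_sig <- post_test$significant
  category <- ifelse(pre_sig & !post_sig, "removed_abnormal",
              ifelse(!pre_sig & post_sig, "new_abnormal",
              ifelse(pre_sig & post_sig, "unchanged_abnormal",
                     "never_abnormal")))
  edges <- data.frame(
    i = pre_test$i, j = pre_test$j,
    region_i = pre_test$region_i, region_j = pre_test$region_j,
    t_pre = pre_test$t, p_pre = pre_test$p,
    t_post = post_test$t, p_post = post_test$p,
    category = category, stringsAsFactors = FALSE)
  lobe_summary <- NULL
  if (!is.null(parc)) {
    stopifnot(inherits(parc, "parcellation"))
    li <- parc$lobe[match(edges$region_i, parc$abbreviation)]
    lj <- parc$lobe[match(edges$region_j, parc$abbreviation)]
    edges$lobe_i <- li
    edges$lobe_j <- lj
    pair <- ifelse(li <= lj, paste(li, lj, sep = " - "),
                   paste(lj, li, sep = " - "))
    lobe_summary <- as.data.frame(table(lobe_pair = pair,
                                        category = edges$category),
                                  stringsAsFactors = FALSE)
    names(lobe_summary)[3] <- "n_edges"
  }
  structure(list(edges = edges, lobe_summary = lobe_summary),
            class = "edge_category_map")
}

#' @export
print.edge_category_map <- function(x, ...) {
  counts <- table(x$edges$category)
  cat("<edge_category_map> ", nrow(x$edges), " edges\n", sep = "")
  for (nm in names(counts)) cat("  ", nm, ": ", counts[[nm]], "\n", sep = "")
  invisible(x)
}

#' Write an edge category map to disk
#'
#' The per-edge table goes to a TSV, the category counts (by lobe pair
#' when available) to a JSON summary.
#'
#' @param map an `edge_category_map`.
#' @param tsv_path,json_path output paths (either may be `NULL` to skip).
#' @export
write_edge_categories <- function(map, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(map, "edge_category_map"))
  if (!is.null(tsv_path)) {
    utils::write.table(map$edges, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    summary <- list(total = as.list(table(map$edges$category)))
    if (!is.null(map$lobe_summary)) summary$by_lobe_pair <- map$lobe_summary
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(map)
}
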