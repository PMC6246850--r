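#' Parcellation tables
#'
#' A parcellation is a data frame with one row per region and columns
#' `index` (1-based, contiguous), `abbreviation` (unique region id used as
#' matrix header), `description`, `lobe`, `hemisphere` (`"L"`/`"R"`) and
#' `pair_id` (integer linking the left/right members of one homologous
#' pair, the unit of bilateral stimulation).  An optional
#' `pair_abbreviation` column names the pair (e.g. `"PAL"` for the globus
#' pallidus); it is derived from `abbreviation` when absent.
#'
#' @param df data frame with the columns above.
#' @return The validated data frame with class `parcellation`.
#' @export
parcellation <- function(df) {
  req <- c("index", "abbreviation", "description", "lobe", "hemisphere", "pair_id")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("parcellation missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  df$index <- as.integer(df$index)
  df$pair_id <- as.integer(df$pair_id)
  if (!identical(df$index, seq_len(nrow(df)))) {
    stop("region indices must be unique and contiguous from 1", call. = FALSE)
  }
  if (anyDuplicated(df$abbreviation)) stop("region abbreviations must be unique", call. = FALSE)
  if (!all(df$hemisphere %in% c("L", "R"))) {
    stop('hemisphere must be "L" or "R"', call. = FALSE)
  }
  # every L region has exactly one R partner sharing its pair_id
  for (p in unique(df$pair_id)) {
    h <- sort(df$hemisphere[df$pair_id == p])
    if (!identical(h, c("L", "R"))) {
      stop("pair_id ", p, " must have exactly one L and one R member", call. = FALSE)
    }
  }
  if (is.null(df$pair_abbreviation)) {
    df$pair_abbreviation <- sub("\\.(L|R)$", "", df$abbreviation)
  }
  class(df) <- c("parcellation", "data.frame")
  df
}

#' Default 92-region parcellation
#'
#' The package's shipped whole-brain parcellation: the 90 cortical and
#' subcortical regions of the AAL atlas plus the bilateral subthalamic
#' nucleus, 46 homologous left/right pairs in total, each region tagged
#' with its lobe (frontal, insular, limbic, occipital, parietal,
#' temporal, basal ganglia).
#'
#' @return A `parcellation` with 92 rows.
#' @export
default_parcellation <- function() {
  path <- system.file("extdata", "parcellation_92.tsv", package = "connstim",
                      mustWork = TRUE)
  read_parcellation(path)
}

#' Read / write a parcellation TSV
#'
#' @param path file path; tab-separated with a header row containing the
#'   columns documented in [parcellation()].
#' @return `read_parcellation()` returns a `parcellation`;
#'   `write_parcellation()` returns `path` invisibly.
#' @export
read_parcellation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  parcellation(df)
}

#' @param parc a `parcellation`.
#' @rdname read_parcellation
#' @export
write_parcellation <- function(parc, path) {
  stopifnot(inherits(parc, "parcellation"))
  utils::write.table(parc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generic synthetic parcellation
#'
#' Builds a minimal valid parcellation for an arbitrary (even) region
#' count, used by the synthetic cohort generator when a non-default
#' region count is requested.  Regions `2k-1` / `2k` form homologous pair
#' `k` (left/right), mirroring the odd/even convention of the default
#' atlas.
#'
#' @param n_regions even number of regions.
#' @return A `parcellation` with `n_regions` rows.
#' @export
synthetic_parcellation <- function(n_regions) {
  if (n_regions %% 2L != 0L || n_regions < 2L) {
    stop("n_regions must be an even number >= 2", call. = FALSE)
  }
  k <- n_regions / 2L
  parcellation(data.frame(
    index = seq_len(n_regions),
    abbreviation = paste0("SYN", rep(seq_len(k), each = 2), c(".L", ".R")),
    description = paste("Synthetic region pair", rep(seq_len(k), each = 2)),
    lobe = "Synthetic",
    hemisphere = rep(c("L", "R"), k),
    pair_id = rep(seq_len(k), each = 2),
    stringsAsFactors = FALSE
  ))
}

# Region indices (L, R) of one homologous pair; accepts a pair_id or a
# pair abbreviation.
pair_indices <- function(parc, pair) {
  stopifnot(inherits(parc, "parcellation"))
  if (is.character(pair)) {
    hit <- unique(parc$pair_id[parc$pair_abbreviation == pair])
    if (length(hit) != 1) stop("unknown target pair abbreviation: ", pair, call. = FALSE)
    pair <- hit
  }
  rows <- which(parc$pair_id == pair)
  if (length(rows) != 2) stop("unknown target pair id: ", pair, call. = FALSE)
  rows[order(parc$hemisphere[rows])]  # L then R
}

# All homologous pairs, in pair_id order.
pair_table <- function(parc) {
  left <- parc[parc$hemisphere == "L", ]
  left <- left[order(left$pair_id), ]
  data.frame(pair_id = left$pair_id,
             pair_abbreviation = left$pair_abbreviation,
             lobe = left$lobe, stringsAsFactors = FALSE)
}
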