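#' Read a target-prediction source file
#'
#' One prediction source is a two-column tab-separated file of predicted
#' (mRNA, miRNA) pairs, one pair per line, no header.
#'
#' @param path file path.
#' @param name source name; defaults to the file name without extension.
#' @return a tibble with columns `mrna_id`, `mirna_id`, `source`; duplicate
#'   pairs within a source are collapsed.
#' @export
read_prediction_source <- function(path, name = NULL) {
  if (!file.exists(path)) abort(paste0("prediction source not found: ", path))
  name <- name %||% sub("\\.[^.]*$", "", basename(path))
  raw <- utils::read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(raw) != 2L) {
    abort(paste0("prediction source ", path, " must have exactly 2 columns"))
  }
  tibble::tibble(mrna_id = raw[[1L]], mirna_id = raw[[2L]], source = name) |>
    dplyr::distinct()
}

#' Build a binary map matrix from prediction sources by a vote rule
#'
#' A (mRNA, miRNA) pair enters the map (entry 1) when it is predicted by at
#' least `min_support` distinct sources — the paper-style "at least two of
#' the four databases" rule is `min_support = 2`. Rows and columns are
#' restricted to the supplied identifier universes (typically the
#' differentially expressed entities).
#'
#' @param sources a list of prediction-source tables as returned by
#'   [read_prediction_source()] (columns `mrna_id`, `mirna_id`; a `source`
#'   column is optional — absent, the list position names the source).
#' @param min_support minimum number of distinct supporting sources.
#' @param mrna_universe,mirna_universe identifier vectors defining the map
#'   matrix rows and columns.
#' @return a [map_matrix()] of shape `length(mrna_universe)` x
#'   `length(mirna_universe)`.
#' @export
build_map_matrix <- function(sources, min_support, mrna_universe,
                             mirna_universe) {
  if (length(sources) == 0L) abort("at least one prediction source is required")
  if (min_support < 1L) abort("min_support must be >= 1")
  if (length(mrna_universe) == 0L || length(mirna_universe) == 0L) {
    abort("identifier universes must be non-empty")
  }
  named <- purrr::imap(sources, function(src, idx) {
    src <- tibble::as_tibble(src)
    if (!"source" %in% names(src)) src$source <- paste0("source_", idx)
    dplyr::distinct(src, .data$mrna_id, .data$mirna_id, .data$source)
  })
  support <- dplyr::bind_rows(named) |>
    dplyr::distinct() |>
    dplyr::count(.data$mrna_id, .data$mirna_id, name = "n_sources") |>
    dplyr::filter(.data$n_sources >= min_support,
                  .data$mrna_id %in% mrna_universe,
                  .data$mirna_id %in% mirna_universe)
  vals <- matrix(0, length(mrna_universe), length(mirna_universe),
                 dimnames = list(mrna_universe, mirna_universe))
  vals[cbind(support$mrna_id, support$mirna_id)] <- 1
  map_matrix(vals)
}

#' Collapse probeset-level expression to one row per entity
#'
#' Microarray platforms measure each miRNA or mRNA through one or more
#' probesets; the entity-level log2 fold-change for each condition is the
#' median over the entity's probesets (midpoint of the central pair for an
#' even count).
#'
#' @param probesets a data frame with columns `probeset_id`, `parent_id`,
#'   and one numeric column per condition.
#' @param parent_ids entities to return, in this row order; every parent
#'   must own at least one probeset.
#' @return an [expression_matrix()] with one row per parent.
#' @export
collapse_probesets <- function(probesets, parent_ids) {
  probesets <- tibble::as_tibble(probesets)
  needed <- c("probeset_id", "parent_id")
  if (!all(needed %in% names(probesets))) {
    abort("probesets must have columns probeset_id and parent_id")
  }
  if (anyDuplicated(probesets$probeset_id)) {
    abort("each probeset must map to exactly one parent")
  }
  missing <- setdiff(parent_ids, probesets$parent_id)
  if (length(missing) > 0L) {
    abort(paste0("no probeset for parent(s): ",
                 paste(utils::head(missing, 10L), collapse = ", ")))
  }
  cond_cols <- setdiff(names(probesets), needed)
  if (length(cond_cols) == 0L) abort("no condition columns found")
  med <- probesets |>
    dplyr::filter(.data$parent_id %in% parent_ids) |>
    dplyr::group_by(.data$parent_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(cond_cols), median),
                     .groups = "drop")
  vals <- as.matrix(med[cond_cols])
  rownames(vals) <- med$parent_id
  expression_matrix(vals[parent_ids, , drop = FALSE])
}
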