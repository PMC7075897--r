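#' Condition labels of a pulldown count table
#'
#' A proximity-labelling experiment is scored in six conditions: each of the
#' two bait fusions (e.g. Usp and EcR) under sham and hormone treatment, plus
#' the unfused labelling-enzyme control under both treatments.
#'
#' @return Character vector of the six condition column names, bait
#'   conditions first.
#' @export
count_conditions <- function() {
  c("bait1_sham", "bait1_20E", "bait2_sham", "bait2_20E",
    "ctrl_sham", "ctrl_20E")
}

bait_conditions <- function() count_conditions()[1:4]
ctrl_conditions <- function() count_conditions()[5:6]

#' Construct a pulldown count table
#'
#' @param df data.frame with columns `gene`, `protein_id`, the six condition
#'   columns of [count_conditions()], and optionally `is_nuclear` (logical).
#' @param technique `"BIOID2"` or `"APEX2"`; the labelling enzyme, which sets
#'   the conventional peptide threshold (10 and 20 respectively).
#' @return A `count_table`: a data.frame with a `technique` attribute.
#' @export
count_table <- function(df, technique = c("BIOID2", "APEX2")) {
  technique <- match.arg(toupper(technique), c("BIOID2", "APEX2"))
  need <- c("gene", "protein_id", count_conditions())
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stopf("count table is missing required column(s): %s",
          paste(missing_cols, collapse = ", "))
  for (cc in count_conditions()) {
    v <- df[[cc]]
    if (is.character(v)) v <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad))
      stopf("column '%s' has a negative or non-integer count at row %d",
            cc, bad[1])
    df[[cc]] <- as.integer(v)
  }
  if (any(!nzchar(df$protein_id)))
    stopf("empty protein_id at row %d", which(!nzchar(df$protein_id))[1])
  if (is.null(df[["is_nuclear"]])) df[["is_nuclear"]] <- rep(NA, nrow(df))
  df <- df[, c(need, "is_nuclear")]
  structure(df, class = c("count_table", "data.frame"),
            technique = technique)
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %d proteins, technique %s\n",
              nrow(x), attr(x, "technique")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Read a pulldown count table from TSV
#'
#' The file must be tab-delimited with a header naming `gene`, `protein_id`
#' and the six condition columns; unknown extra columns are ignored with a
#' warning.  An optional nuclear-annotation file (one accession per line)
#' sets the `is_nuclear` flag.
#'
#' @param path TSV file path.
#' @inheritParams count_table
#' @param nuclear_ids optional path to a plain-text list of nuclear protein
#'   accessions, or a character vector of accessions.
#' @return A [count_table()].
#' @export
read_count_table <- function(path, technique = c("BIOID2", "APEX2"),
                             nuclear_ids = NULL) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  extra <- setdiff(names(df), c("gene", "protein_id", count_conditions(),
                                "is_nuclear"))
  if (length(extra)) {
    warning(sprintf("ignoring unrecognised column(s): %s",
                    paste(extra, collapse = ", ")), call. = FALSE)
    df <- df[, setdiff(names(df), extra), drop = FALSE]
  }
  tab <- count_table(df, technique)
  if (!is.null(nuclear_ids)) {
    ids <- if (length(nuclear_ids) == 1 && file.exists(nuclear_ids))
      readLines(nuclear_ids) else as.character(nuclear_ids)
    tab$is_nuclear <- tab$protein_id %in% trimws(ids)
  }
  tab
}

#' Write a count table (or selected candidates) to TSV
#'
#' @param x a [count_table()] or the result of [select_candidates()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Maximum peptide count over the bait conditions
#'
#' Selection criterion one asks for a minimum number of detected peptides in
#' at least one of the four bait conditions; control conditions are excluded.
#'
#' @param table a [count_table()].
#' @return Integer vector, one value per protein.
#' @export
max_bait_count <- function(table) {
  m <- as.matrix(as.data.frame(table)[, bait_conditions()])
  as.integer(unname(apply(m, 1L, max)))
}

#' Enrichment over the maximal negative control
#'
#' Selection criterion two: the best bait-condition count divided by the
#' maximum of the two labelling-enzyme-only control counts.  With
#' `per_condition = TRUE` each bait condition is instead compared to the
#' control of its own treatment arm.  When the control denominator (plus
#' pseudocount) is zero and some bait count is positive, the ratio is the
#' `Inf` sentinel: zero-control proteins always clear a finite threshold.
#'
#' @inheritParams max_bait_count
#' @param pseudocount non-negative value added to the control denominator
#'   only (default 1).
#' @param per_condition compare each bait condition to the matching-treatment
#'   control rather than to the maximum over both controls.
#' @return Numeric vector of enrichment ratios (possibly `Inf`).
#' @export
control_enrichment <- function(table, pseudocount = 1, per_condition = FALSE) {
  stopifnot(pseudocount >= 0)
  df <- as.data.frame(table)
  baits <- as.matrix(df[, bait_conditions()])
  if (per_condition) {
    denom <- cbind(df$ctrl_sham, df$ctrl_20E,
                   df$ctrl_sham, df$ctrl_20E) + pseudocount
    ratios <- baits / denom
    ratios[baits == 0 & denom == 0] <- 0
    unname(apply(ratios, 1L, max))
  } else {
    denom <- pmax(df$ctrl_sham, df$ctrl_20E) + pseudocount
    best <- unname(apply(baits, 1L, max))
    r <- best / denom
    r[best == 0 & denom == 0] <- 0
    r
  }
}

#' Filter configuration for candidate selection
#'
#' Houses the published selection criteria: a peptide-count threshold (10
#' for BioID2, 20 for APEX2) on the best bait condition, a minimum
#' enrichment of 2.5 over the maximal negative control, and an optional
#' requirement for prior nuclear annotation.
#'
#' @param technique `"BIOID2"` or `"APEX2"`; supplies the conventional
#'   `min_peptides` when that is not given.
#' @param min_peptides peptide-count threshold, compared as `>=`.
#' @param min_enrichment enrichment threshold (default 2.5).
#' @param pseudocount see [control_enrichment()].
#' @param require_nuclear keep only proteins flagged as nuclear.
#' @param strict_enrichment if `TRUE` the enrichment comparison is strict
#'   (`>`); the default `FALSE` uses `>=`, the reading consistent with the
#'   published tables (two listed proteins sit exactly at 2.5).
#' @param per_condition_control see [control_enrichment()].
#' @return A `filter_config` list.
#' @export
filter_config <- function(technique = c("BIOID2", "APEX2"),
                          min_peptides = NULL, min_enrichment = 2.5,
                          pseudocount = 1, require_nuclear = TRUE,
                          strict_enrichment = FALSE,
                          per_condition_control = FALSE) {
  technique <- match.arg(toupper(technique), c("BIOID2", "APEX2"))
  if (is.null(min_peptides))
    min_peptides <- if (technique == "APEX2") 20L else 10L
  stopifnot(min_peptides >= 1, min_enrichment > 1, pseudocount >= 0)
  structure(list(technique = technique,
                 min_peptides = as.integer(min_peptides),
                 min_enrichment = min_enrichment,
                 pseudocount = pseudocount,
                 require_nuclear = isTRUE(require_nuclear),
                 strict_enrichment = isTRUE(strict_enrichment),
                 per_condition_control = isTRUE(per_condition_control)),
            class = "filter_config")
}

#' Select candidate bait partners from a count table
#'
#' Applies the three selection criteria jointly: enough peptides in at least
#' one bait condition, sufficient enrichment over the maximal negative
#' control, and (optionally) prior nuclear annotation.  Input order is
#' preserved and the result is deterministic.
#'
#' @inheritParams max_bait_count
#' @param config a [filter_config()]; defaults to the conventions of the
#'   table's technique.
#' @return The selected rows of `table` with two extra columns,
#'   `max_bait_count` and `control_enrichment`.
#' @export
select_candidates <- function(table, config = filter_config(attr(table, "technique"))) {
  stopifnot(inherits(config, "filter_config"))
  mb <- max_bait_count(table)
  ce <- control_enrichment(table, config$pseudocount,
                           config$per_condition_control)
  keep <- mb >= config$min_peptides
  keep <- keep & if (config$strict_enrichment) ce > config$min_enrichment
                 else ce >= config$min_enrichment
  if (config$require_nuclear) {
    if (all(is.na(table$is_nuclear)))
      stopf("require_nuclear = TRUE but no nuclear annotation is present")
    keep <- keep & !is.na(table$is_nuclear) & table$is_nuclear
  }
  out <- as.data.frame(table)[keep, , drop = FALSE]
  out$max_bait_count <- mb[keep]
  out$control_enrichment <- ce[keep]
  rownames(out) <- NULL
  structure(out, class = c("count_table", "data.frame"),
            technique = attr(table, "technique"))
}

#' Top-3 peptide-area fold change between treatments
#'
#' Label-free quantification by the mean peak area of the three most intense
#' peptides per protein.  The fold change is the treated over sham ratio of
#' top-3 means (each offset by `pseudo_area`), and a protein is flagged
#' "changed" when the fold change or its reciprocal exceeds
#' `change_threshold` (default 2; quantitative shifts below two-fold are
#' treated as within-noise).
#'
#' @param areas_sham,areas_20E numeric vectors of peptide peak areas (any
#'   length; fewer than three areas are averaged as-is).
#' @param pseudo_area non-negative offset added to both top-3 means.
#' @param change_threshold fold-change magnitude regarded as a real change.
#' @param protein_id optional identifier carried through to the result.
#' @return A one-row data.frame with `top3_area_sham`, `top3_area_20E`,
#'   `fold_change`, `changed` and `quantifiable`.
#' @export
top3_fold_change <- function(areas_sham, areas_20E, pseudo_area = 0,
                             change_threshold = 2, protein_id = NA_character_) {
  top3 <- function(x) if (length(x) == 0) 0 else
    mean(sort(x, decreasing = TRUE)[seq_len(min(3L, length(x)))])
  stopifnot(all(areas_sham >= 0), all(areas_20E >= 0), pseudo_area >= 0)
  s <- top3(areas_sham); t <- top3(areas_20E)
  denom <- s + pseudo_area
  quantifiable <- denom > 0
  fc <- if (quantifiable) (t + pseudo_area) / denom else NA_real_
  changed <- quantifiable && is.finite(fc) &&
    (fc > change_threshold || (fc > 0 && 1 / fc > change_threshold))
  data.frame(protein_id = protein_id, top3_area_sham = s, top3_area_20E = t,
             fold_change = fc, changed = changed, quantifiable = quantifiable)
}
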