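# Plain-text readers/writers for the pipeline's interchange formats.

#' Read a peak table from CSV
#'
#' Long-format CSV with the columns documented in [peak_table()].
#'
#' @param path CSV file path.
#' @return A `peak_table`.
#' @export
read_peak_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("clone_id" %in% names(df)) df$clone_id <- as.character(df$clone_id)
  peak_table(df)
}

#' Write a peak table to CSV
#'
#' @param pt a `peak_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(pt, path) {
  utils::write.csv(as.data.frame(pt), path, row.names = FALSE)
  invisible(path)
}

#' Write an ontology as a TSV edge list
#'
#' Columns `source`, `relation`, `target` with a header; readable by
#' [load_ontology()] with the `tsv_edges` dialect. Terms with no edges do
#' not survive the round trip, since the TSV reader registers only edge
#' endpoints.
#'
#' @param g an `ontology_graph`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_ontology_tsv <- function(g, path) {
  utils::write.table(g$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an SLC annotation table from CSV
#'
#' Wide CSV with columns `slc`, `family`, `fold`, `localization`,
#' `substrate_class`, `ion_coupling`, `substrates`; multi-valued fields are
#' semicolon-separated, `substrates` may be empty (orphan SLC).
#'
#' @param path CSV file path.
#' @return Data frame with a `substrates` list column.
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"slc" %in% names(df)) stop("annotation table needs an 'slc' column")
  if ("substrates" %in% names(df)) {
    df$substrates <- lapply(strsplit(ifelse(is.na(df$substrates), "",
                                            df$substrates), ";"),
                            function(x) x[nzchar(x)])
  } else {
    df$substrates <- rep(list(character()), nrow(df))
  }
  df
}

#' Write an SLC annotation table to CSV
#'
#' @param ann annotation data frame (list columns are joined with `;`).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  df <- as.data.frame(ann)
  for (col in names(df)) {
    if (is.list(df[[col]])) {
      df[[col]] <- vapply(df[[col]], paste, character(1), collapse = ";")
    }
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Convert a wide annotation table to long (class, property) format
#'
#' Expands the multi-valued functional-property columns (`family`, `fold`,
#' `localization`, `substrate_class`, `ion_coupling`) into rows of
#' (`slc`, `class`, `property`) as consumed by [enrich_properties()].
#'
#' @param ann wide annotation data frame.
#' @return Long data frame with columns `slc`, `class`, `property`.
#' @export
annotation_long <- function(ann) {
  classes <- intersect(c("family", "fold", "localization", "substrate_class",
                         "ion_coupling"), names(ann))
  if (length(classes) == 0L) stop("no functional-property column found")
  rows <- list()
  for (cls in classes) {
    for (i in seq_len(nrow(ann))) {
      vals <- ann[[cls]][[i]]
      if (is.character(vals) && length(vals) == 1L) {
        vals <- strsplit(ifelse(is.na(vals), "", vals), ";")[[1L]]
      }
      vals <- vals[nzchar(vals)]
      for (v in vals) {
        rows[[length(rows) + 1L]] <- data.frame(slc = ann$slc[[i]],
                                                class = cls, property = v,
                                                stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 for identical partitions, about 0 for independent ones.
#'
#' @param a,b label vectors over the same items (matched by name when both
#'   are named, by position otherwise).
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    common <- intersect(names(a), names(b))
    a <- a[common]; b <- b[common]
  }
  stopifnot(length(a) == length(b), length(a) > 0L)
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  expected <- sum_i * sum_j / choose(n, 2)
  max_idx <- (sum_i + sum_j) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
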