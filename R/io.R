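#' Read a three-library count table
#'
#' The counts file is tab-separated with a required header and columns
#' `gene_id`, `length_bp`, `count_P1`, `count_P2`, `count_F1`; lines starting
#' with `#` are ignored. Library sizes (total mapped reads per library) are
#' never inferred from column sums -- counts are uniquely-mapped reads only,
#' so column sums undercount the library -- and must be supplied either as a
#' named vector or as a YAML/JSON sidecar file with keys `P1`, `P2`, `F1`.
#'
#' @param path Path to the counts TSV.
#' @param lib_sizes Either a named numeric vector `c(P1=, P2=, F1=)` or the
#'   path to a YAML/JSON file with those keys.
#' @return A `count_table` tibble (columns as above) carrying the library
#'   sizes as the `lib_sizes` attribute; row order preserved.
#' @export
read_count_table <- function(path, lib_sizes) {
  stopifnot(file.exists(path))
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  needed <- c("gene_id", "length_bp", "count_P1", "count_P2", "count_F1")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop("counts file is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  tbl <- dplyr::mutate(
    raw[needed],
    dplyr::across(-"gene_id", ~ suppressWarnings(as.numeric(.x)))
  )
  count_table(tbl, lib_sizes = resolve_lib_sizes(lib_sizes))
}

resolve_lib_sizes <- function(lib_sizes) {
  if (is.character(lib_sizes) && length(lib_sizes) == 1) {
    stopifnot(file.exists(lib_sizes))
    parsed <- if (grepl("\\.json$", lib_sizes)) {
      jsonlite::read_json(lib_sizes, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(lib_sizes)
    }
    lib_sizes <- unlist(parsed)
  }
  lib_sizes <- lib_sizes[c("P1", "P2", "F1")]
  if (anyNA(lib_sizes)) {
    stop("library sizes must name P1, P2 and F1", call. = FALSE)
  }
  storage.mode(lib_sizes) <- "double"
  lib_sizes
}

#' Construct and validate a count table
#'
#' Validation enforces the container's invariants: non-negative integer
#' counts, lengths of at least 1 bp, unique gene identifiers, and each
#' library size at least as large as that library's largest per-gene count.
#' Error messages name the offending gene.
#'
#' @param tbl Data frame with columns `gene_id`, `length_bp`, `count_P1`,
#'   `count_P2`, `count_F1`.
#' @param lib_sizes Named numeric vector with entries `P1`, `P2`, `F1`.
#' @return A validated `count_table` tibble.
#' @export
count_table <- function(tbl, lib_sizes) {
  tbl <- tibble::as_tibble(tbl)
  lib_sizes <- resolve_lib_sizes(lib_sizes)
  if (any(lib_sizes < 1)) stop("library sizes must be positive", call. = FALSE)
  count_cols <- c("count_P1", "count_P2", "count_F1")
  for (col in count_cols) {
    v <- tbl[[col]]
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad) > 0) {
      stop("invalid count in ", col, " for gene_id ",
           paste(tbl$gene_id[bad[1]]), " (counts must be non-negative integers)",
           call. = FALSE)
    }
  }
  bad_len <- which(is.na(tbl$length_bp) | tbl$length_bp < 1)
  if (length(bad_len) > 0) {
    stop("invalid length_bp for gene_id ", tbl$gene_id[bad_len[1]], call. = FALSE)
  }
  dup <- tbl$gene_id[duplicated(tbl$gene_id)]
  if (length(dup) > 0) {
    stop("duplicate gene_id: ", dup[1], call. = FALSE)
  }
  for (lib in c("P1", "P2", "F1")) {
    mx <- max(tbl[[paste0("count_", lib)]], 0)
    if (lib_sizes[[lib]] < mx) {
      stop("library size for ", lib, " (", lib_sizes[[lib]],
           ") is smaller than its largest per-gene count (", mx, ")",
           call. = FALSE)
    }
  }
  attr(tbl, "lib_sizes") <- lib_sizes
  class(tbl) <- c("mp_count_table", class(tbl))
  tbl
}

#' Library sizes attached to a count table
#' @param x A `count_table`.
#' @return Named numeric vector `c(P1=, P2=, F1=)`.
#' @export
lib_sizes <- function(x) {
  ls <- attr(x, "lib_sizes")
  if (is.null(ls)) stop("object carries no lib_sizes attribute", call. = FALSE)
  ls
}

.chromosome_levels <- c(sprintf("A%02d", 1:10), sprintf("C%02d", 1:9), "unplaced")

#' Read a gene annotation table
#'
#' Tab-separated with columns `gene_id` and `chromosome`; optional
#' `go_terms` (semicolon-joined GO identifiers) and `is_te` / `te_family`.
#' The subgenome is derived from the chromosome: `A` for A01-A10 (the
#' *B. rapa*-derived complement), `C` for C01-C09 (*B. oleracea*-derived),
#' `unassigned` for unplaced genes.
#'
#' @param path Path to the annotation TSV.
#' @param strict If `FALSE` (default), unknown chromosome labels are demoted
#'   to `"unplaced"` with a warning; if `TRUE` they are an error.
#' @return An `annotation` tibble with columns `gene_id`, `chromosome`,
#'   `subgenome`, `go_terms` (list column of character vectors), `is_te`,
#'   `te_family`.
#' @export
read_annotation <- function(path, strict = FALSE) {
  stopifnot(file.exists(path))
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("gene_id", "chromosome") %in% names(raw))) {
    stop("annotation file needs gene_id and chromosome columns", call. = FALSE)
  }
  annotation_table(
    gene_id = raw$gene_id,
    chromosome = raw$chromosome,
    go_terms = if ("go_terms" %in% names(raw)) raw$go_terms else NA_character_,
    is_te = if ("is_te" %in% names(raw)) tolower(raw$is_te) %in% c("true", "yes", "1") else FALSE,
    te_family = if ("te_family" %in% names(raw)) raw$te_family else NA_character_,
    strict = strict
  )
}

#' Build an annotation tibble from vectors
#'
#' @param gene_id Character vector of gene identifiers.
#' @param chromosome Chromosome labels (A01..A10, C01..C09, "unplaced").
#' @param go_terms Semicolon-joined GO identifier strings (or a list of
#'   character vectors); `NA`/empty means unannotated.
#' @param is_te Logical TE flag.
#' @param te_family Free-text TE family, `NA` if none.
#' @param strict Error (rather than warn + demote) on unknown chromosomes.
#' @return An `annotation` tibble; see [read_annotation()].
#' @export
annotation_table <- function(gene_id, chromosome, go_terms = NA_character_,
                             is_te = FALSE, te_family = NA_character_,
                             strict = FALSE) {
  n <- length(gene_id)
  chromosome <- as.character(rep_len(chromosome, n))
  unknown <- !(chromosome %in% .chromosome_levels)
  if (any(unknown)) {
    if (strict) {
      stop("unknown chromosome label(s): ",
           paste(unique(chromosome[unknown]), collapse = ", "), call. = FALSE)
    }
    warning("demoting ", sum(unknown), " unknown chromosome label(s) to 'unplaced'",
            call. = FALSE)
    chromosome[unknown] <- "unplaced"
  }
  if (!is.list(go_terms)) {
    go_terms <- purrr::map(rep_len(as.character(go_terms), n), function(s) {
      if (is.na(s) || !nzchar(s)) character(0) else unique(strsplit(s, ";", fixed = TRUE)[[1]])
    })
  } else {
    go_terms <- purrr::map(rep_len(go_terms, n), unique)
  }
  out <- tibble::tibble(
    gene_id = gene_id,
    chromosome = chromosome,
    subgenome = dplyr::case_when(
      startsWith(chromosome, "A") ~ "A",
      startsWith(chromosome, "C") ~ "C",
      .default = "unassigned"
    ),
    go_terms = go_terms,
    is_te = rep_len(as.logical(is_te), n),
    te_family = rep_len(as.character(te_family), n)
  )
  class(out) <- c("mp_annotation", class(out))
  out
}

#' Write a result table to disk
#'
#' Tab-separated by default with a `# midparent: <class>` comment line so the
#' matching [read_results()] restores the result class; `format = "jsonl"`
#' writes one JSON object per line instead. List columns (e.g. GO term sets)
#' are semicolon-joined in TSV output. Round trip is lossless.
#'
#' @param records A tibble of one result type.
#' @param path Output path.
#' @param format `"tsv"` (default) or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path, format = c("tsv", "jsonl")) {
  format <- match.arg(format)
  if (!is.data.frame(records)) {
    stop("write_results() expects a data frame of one result type", call. = FALSE)
  }
  tag <- setdiff(class(records), c("tbl_df", "tbl", "data.frame"))
  tag <- if (length(tag) > 0) tag[1] else "tbl_df"
  flat <- dplyr::mutate(tibble::as_tibble(records), dplyr::across(
    dplyr::where(is.list), ~ purrr::map_chr(.x, paste, collapse = ";")
  ))
  if (format == "jsonl") {
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines(paste0("{\"midparent_class\":\"", tag, "\"}"), con)
    jsonlite::stream_out(flat, con, verbose = FALSE)
  } else {
    writeLines(paste0("# midparent: ", tag), path)
    suppressMessages(readr::write_tsv(flat, path, append = TRUE, col_names = TRUE))
  }
  invisible(path)
}

#' Read back a result table written by [write_results()]
#'
#' @param path Path to a TSV written by [write_results()].
#' @param list_cols Character vector of column names to split back into list
#'   columns on `";"` (default `"go_terms"` when present).
#' @return The result tibble with its class tag restored.
#' @export
read_results <- function(path, list_cols = "go_terms") {
  stopifnot(file.exists(path))
  first <- readLines(path, n = 1)
  tag <- sub("^# midparent: ", "", first)
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  for (col in intersect(list_cols, names(tbl))) {
    tbl[[col]] <- purrr::map(as.character(tbl[[col]]), function(s) {
      if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, ";", fixed = TRUE)[[1]]
    })
  }
  if (tag != "tbl_df" && nzchar(tag)) class(tbl) <- c(tag, class(tbl))
  tbl
}

#' Write a count table plus its library-size sidecar
#'
#' @param counts A `count_table`.
#' @param path Counts TSV path.
#' @param sizes_path Optional YAML sidecar path for the library sizes
#'   (default: `path` with a `.sizes.yaml` suffix).
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path, sizes_path = NULL) {
  stopifnot(inherits(counts, "mp_count_table"))
  if (is.null(sizes_path)) sizes_path <- paste0(path, ".sizes.yaml")
  readr::write_tsv(tibble::as_tibble(unclass_tbl(counts)), path)
  yaml::write_yaml(as.list(lib_sizes(counts)), sizes_path)
  invisible(path)
}

unclass_tbl <- function(x) {
  class(x) <- c("tbl_df", "tbl", "data.frame")
  attr(x, "lib_sizes") <- NULL
  x
}
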