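#' Read a Y-STR haplotype table
#'
#' Reads a delimited text file with a mandatory header row naming the locus
#' columns. Two layouts are accepted: one row per individual, or one row per
#' distinct haplotype with a `count` column giving its multiplicity (the
#' table is expanded to one row per individual on read). A `population`
#' column is required unless `population` is supplied; `id` and `group`
#' columns are optional and `id` is generated when absent.
#'
#' @param path Path to a tab- or comma-delimited UTF-8 text file. The
#'   delimiter is auto-detected from the header line (tab preferred).
#' @param loci Optional explicit locus columns; by default every column
#'   other than `id`, `population`, `group`, `count`.
#' @param missing `"drop"` (default) removes individuals with missing repeat
#'   values with a warning; `"error"` is a strict mode that fails instead.
#'   Every statistic in the package assumes complete haplotypes.
#' @param population Population label to assign when the file has no
#'   `population` column.
#' @return A tibble with columns `id`, `population` (and `group` if
#'   present), one integer column per locus, and a `"loci"` attribute.
#' @seealso [write_haplotype_table()]
#' @export
read_haplotype_table <- function(path, loci = NULL,
                                 missing = c("drop", "error"),
                                 population = NULL) {
  missing <- match.arg(missing)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0 || !nzchar(trimws(header))) {
    abort(paste0("Empty haplotype table: ", path))
  }
  delim <- if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else "\t"
  data <- readr::read_delim(
    path,
    delim = delim, comment = "#", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  if (nrow(data) == 0) abort(paste0("Haplotype table has no rows: ", path))
  names(data) <- trimws(names(data))
  if (!("population" %in% names(data))) {
    if (is.null(population)) {
      abort("Haplotype table needs a 'population' column (or supply `population`).")
    }
    data$population <- population
  }
  loci <- str_loci(data, loci)
  data <- validate_haplotypes(data, loci, missing = missing, context = path)
  if ("count" %in% names(data)) {
    cnt <- suppressWarnings(as.integer(data$count))
    if (any(is.na(cnt)) || any(cnt < 1)) {
      abort("'count' column must contain positive integers.")
    }
    data$count <- cnt
    data <- tidyr::uncount(data, weights = .data$count)
  }
  if (!("id" %in% names(data))) {
    data$id <- sprintf("ind%04d", seq_len(nrow(data)))
  }
  keep <- intersect(c("id", "population", "group"), names(data))
  out <- tibble::as_tibble(data[c(keep, loci)])
  attr(out, "loci") <- loci
  out
}

#' Write a Y-STR haplotype table
#'
#' Writes one row per individual in the same delimited layout accepted by
#' [read_haplotype_table()]; a read of the written file reproduces the table
#' field for field.
#'
#' @param data Haplotype data frame.
#' @param path Output path.
#' @param delim Field delimiter (tab by default).
#' @param loci Optional explicit locus columns.
#' @return `path`, invisibly.
#' @export
write_haplotype_table <- function(data, path, delim = "\t", loci = NULL) {
  loci <- str_loci(data, loci)
  keep <- intersect(c("id", "population", "group"), names(data))
  readr::write_delim(data[c(keep, loci)], path, delim = delim)
  invisible(path)
}

#' Haplogroup carrier frequencies
#'
#' Turns a per-population table of haplogroup carrier counts into
#' frequencies, e.g. the fraction of typed males carrying H1a1a-M82.
#'
#' @param counts Data frame with columns `population`, `carriers`, `total`.
#' @return The input as a tibble with a `frequency` column in `[0, 1]`.
#' @examples
#' haplogroup_frequency(
#'   data.frame(population = "A", carriers = 20, total = 100)
#' )
#' @export
haplogroup_frequency <- function(counts) {
  counts <- tibble::as_tibble(counts)
  need <- c("population", "carriers", "total")
  missing <- setdiff(need, names(counts))
  if (length(missing) > 0) {
    abort(paste0("Missing columns: ", paste(missing, collapse = ", ")))
  }
  if (any(counts$carriers < 0) || any(counts$total <= 0)) {
    abort("Carrier counts must be >= 0 and totals > 0.")
  }
  if (any(counts$carriers > counts$total)) {
    bad <- counts$population[counts$carriers > counts$total][1]
    abort(paste0("More carriers than typed individuals in ", bad, "."))
  }
  dplyr::mutate(counts, frequency = .data$carriers / .data$total)
}
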