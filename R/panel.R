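#' Locus panels for Y-STR haplotype tables
#'
#' A haplotype table is an ordinary data frame with one row per sampled
#' individual, a `population` column (and optionally `id` and `group`
#' columns), and one integer column per STR locus. The *panel* is simply the
#' ordered character vector of locus column names. `yfiler_panel()` returns
#' the 17 loci of the standard Yfiler multiplex; `str_loci()` resolves the
#' panel of a table, either from an explicit argument, a `"loci"` attribute,
#' or by taking every column that is not one of the reserved metadata
#' columns (`id`, `population`, `group`, `count`).
#'
#' @param data A haplotype data frame.
#' @param loci Optional explicit character vector of locus columns.
#' @return A character vector of locus names.
#' @examples
#' yfiler_panel()
#' @export
yfiler_panel <- function() {
  c(
    "DYS19", "DYS389I", "DYS389II", "DYS390", "DYS391", "DYS392", "DYS393",
    "DYS385a", "DYS385b", "DYS437", "DYS438", "DYS439", "DYS448", "DYS456",
    "DYS458", "DYS635", "YGATAH4"
  )
}

.reserved_cols <- c("id", "population", "group", "count")

#' @rdname yfiler_panel
#' @export
str_loci <- function(data, loci = NULL) {
  if (!is.null(loci)) {
    missing <- setdiff(loci, names(data))
    if (length(missing) > 0) {
      abort(paste0(
        "Loci not present in data: ", paste(missing, collapse = ", ")
      ))
    }
    return(loci)
  }
  att <- attr(data, "loci", exact = TRUE)
  if (!is.null(att)) {
    return(str_loci(data, att))
  }
  loci <- setdiff(names(data), .reserved_cols)
  if (length(loci) == 0) {
    abort("No locus columns found in haplotype data.")
  }
  loci
}

#' Panel derivation rules
#'
#' Rules that turn a raw genotyping panel into the analysis panel. The
#' defaults implement the conventional treatment of Yfiler data in
#' haplotype-based analyses: the multicopy loci DYS385a/b are dropped
#' (alleles at a duplicated locus cannot be assigned to a copy, so step
#' distances are undefined), and DYS389II -- which is genotyped as a
#' fragment containing DYS389I -- is replaced by DYS389II minus DYS389I so
#' that each locus counts mutations once. This takes the 17-locus Yfiler
#' panel to the 15 loci used for diversity, network and dating analyses.
#'
#' @param drop Character vector of loci to exclude.
#' @param adjust_dys389 Logical; subtract DYS389I from DYS389II when both are
#'   present.
#' @return A list of class `panel_rules`.
#' @export
panel_rules <- function(drop = c("DYS385a", "DYS385b"), adjust_dys389 = TRUE) {
  structure(
    list(drop = as.character(drop), adjust_dys389 = isTRUE(adjust_dys389)),
    class = "panel_rules"
  )
}

#' Derive the analysis panel from a raw panel
#'
#' @param raw_panel Character vector of raw locus names (e.g.
#'   [yfiler_panel()]).
#' @param rules A [panel_rules()] object.
#' @return The analysis panel: a character vector of locus names.
#' @details Dropping loci that are absent from `raw_panel` is an error;
#'   `adjust_dys389` leaves the panel names unchanged (the adjustment acts on
#'   values, see [apply_panel_rules()]) and requires both DYS389 loci if any
#'   is present. Applying the same rules twice is a no-op.
#' @examples
#' derive_analysis_panel(yfiler_panel())
#' @export
derive_analysis_panel <- function(raw_panel, rules = panel_rules()) {
  stopifnot(inherits(rules, "panel_rules"))
  drop <- intersect(rules$drop, raw_panel)
  absent <- setdiff(rules$drop, raw_panel)
  # The default DYS385a/b drop must be idempotent (re-deriving an already
  # derived panel is a no-op), so their absence is never an error; any other
  # absent locus in a drop rule is a misconfiguration.
  if (length(setdiff(absent, c("DYS385a", "DYS385b"))) > 0) {
    abort(paste0(
      "Rule refers to loci absent from panel: ",
      paste(absent, collapse = ", "),
      ". Panel: ", paste(raw_panel, collapse = ", ")
    ))
  }
  setdiff(raw_panel, drop)
}

#' Apply panel rules to a haplotype table
#'
#' Drops excluded locus columns and applies the DYS389II := DYS389II -
#' DYS389I adjustment to the values. The returned table carries the derived
#' panel in its `"loci"` attribute.
#'
#' @param data Haplotype data frame.
#' @param rules A [panel_rules()] object.
#' @param loci Optional explicit raw panel.
#' @return The adjusted haplotype table (a tibble).
#' @export
apply_panel_rules <- function(data, rules = panel_rules(), loci = NULL) {
  stopifnot(inherits(rules, "panel_rules"))
  raw <- str_loci(data, loci)
  out <- tibble::as_tibble(data)
  if (rules$adjust_dys389 && "DYS389II" %in% raw) {
    if (!("DYS389I" %in% raw)) {
      abort("DYS389II adjustment requires DYS389I in the panel.")
    }
    if (!isTRUE(attr(data, "dys389_adjusted", exact = TRUE))) {
      out$DYS389II <- out$DYS389II - out$DYS389I
      if (any(out$DYS389II < 0)) {
        abort("DYS389II - DYS389I produced negative repeat counts.")
      }
    }
  }
  panel <- derive_analysis_panel(raw, rules)
  out <- out[c(intersect(.reserved_cols, names(out)), panel)]
  attr(out, "loci") <- panel
  if (rules$adjust_dys389 && "DYS389II" %in% panel) {
    attr(out, "dys389_adjusted") <- TRUE
  }
  out
}

# Validate locus columns: integer-valued, non-negative, no NA.
# Returns data with locus columns cast to integer.
validate_haplotypes <- function(data, loci,
                                missing = c("drop", "error"),
                                context = "haplotype data") {
  missing <- match.arg(missing)
  data <- tibble::as_tibble(data)
  bad_rows <- integer(0)
  for (lc in loci) {
    v <- data[[lc]]
    if (is.character(v)) {
      suppressWarnings(v_num <- as.numeric(v))
      if (any(is.na(v_num) & !is.na(v) & v != "")) {
        i <- which(is.na(v_num) & !is.na(v) & v != "")[1]
        abort(paste0(
          "Non-numeric repeat value ", dQuote(v[i]), " at row ", i,
          ", locus ", lc, " in ", context, "."
        ))
      }
      v <- v_num
    }
    if (!is.numeric(v)) {
      abort(paste0("Locus column ", lc, " is not numeric in ", context, "."))
    }
    nn <- v[!is.na(v)]
    if (any(nn != round(nn))) {
      i <- which(!is.na(v) & v != round(v))[1]
      abort(paste0(
        "Non-integer repeat value ", v[i], " at row ", i, ", locus ", lc,
        " in ", context, ". Intermediate alleles are not supported."
      ))
    }
    if (any(nn < 0)) {
      i <- which(!is.na(v) & v < 0)[1]
      abort(paste0(
        "Negative repeat count at row ", i, ", locus ", lc, "."
      ))
    }
    bad_rows <- union(bad_rows, which(is.na(v)))
    data[[lc]] <- as.integer(round(v))
  }
  if (length(bad_rows) > 0) {
    if (missing == "error") {
      abort(paste0(
        length(bad_rows), " row(s) with missing repeat values in ", context,
        " (strict mode)."
      ))
    }
    warn(paste0(
      "Dropping ", length(bad_rows),
      " row(s) with missing repeat values; all statistics assume complete ",
      length(loci), "-locus haplotypes."
    ))
    data <- data[-sort(bad_rows), , drop = FALSE]
  }
  if (nrow(data) == 0) {
    abort(paste0("No complete haplotypes left in ", context, "."))
  }
  data
}

# Integer matrix of repeat counts (rows = individuals) from a haplotype table.
hap_matrix <- function(data, loci = NULL) {
  loci <- str_loci(data, loci)
  m <- as.matrix(data[loci])
  storage.mode(m) <- "integer"
  m
}

# Reference haplotype (named numeric vector in panel order) from a vector or
# one-row data frame; errors on panel mismatch.
ref_haplotype <- function(ref, loci) {
  if (is.data.frame(ref)) {
    if (nrow(ref) != 1) abort("Reference haplotype must be a single row.")
    missing <- setdiff(loci, names(ref))
    if (length(missing) > 0) {
      abort(paste0(
        "Reference haplotype panel mismatch; missing loci: ",
        paste(missing, collapse = ", ")
      ))
    }
    ref <- unlist(ref[loci])
  }
  ref <- unlist(ref)
  if (!is.null(names(ref))) {
    missing <- setdiff(loci, names(ref))
    if (length(missing) > 0) {
      abort(paste0(
        "Reference haplotype panel mismatch; missing loci: ",
        paste(missing, collapse = ", ")
      ))
    }
    ref <- ref[loci]
  } else if (length(ref) != length(loci)) {
    abort(paste0(
      "Reference haplotype has ", length(ref), " loci; panel has ",
      length(loci), "."
    ))
  }
  as.numeric(ref)
}
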