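#' Column-name dialect for GWAS summary-statistics files
#'
#' Maps the canonical column names used throughout the package to the column
#' names found in a particular summary-statistics file. The mandatory columns
#' are `variant_id`, `effect_allele`, `other_allele`, `beta`, `se` and `pval`;
#' `chrom`, `pos`, `eaf`, `n`, `n_case` and `n_control` are optional.
#'
#' @param ... Named character scalars overriding the defaults, e.g.
#'   `variant_id = "SNP"`, `beta = "b"`.
#' @return A named character vector (canonical name -> file column name).
#' @examples
#' sumstats_dialect(variant_id = "SNP", pval = "p")
#' @export
sumstats_dialect <- function(...) {
  default <- c(
    variant_id = "variant_id", chrom = "chrom", pos = "pos",
    effect_allele = "effect_allele", other_allele = "other_allele",
    eaf = "eaf", beta = "beta", se = "se", pval = "pval",
    n = "n", n_case = "n_case", n_control = "n_control"
  )
  override <- c(...)
  if (length(override)) {
    bad <- setdiff(names(override), names(default))
    if (length(bad)) {
      abort(glue::glue("unknown dialect field(s): {paste(bad, collapse = ', ')}"),
            class = "metabomr_config_error")
    }
    default[names(override)] <- override
  }
  default
}

MANDATORY_COLS <- c("variant_id", "effect_allele", "other_allele", "beta", "se", "pval")
VALID_BASES <- c("A", "C", "G", "T")

#' Validate a table of variant associations
#'
#' Applies the row-level invariants every variant association must satisfy:
#' alleles are single bases from A/C/G/T and differ from each other, `se > 0`,
#' `pval` in (0, 1], `eaf` in \[0, 1\] when present, `pos >= 1` when present.
#' Alleles are uppercased before checking. Rows failing any invariant are
#' removed and reported.
#'
#' @param data A data frame of variant associations in canonical columns.
#' @return The validated tibble, with a `"rejected"` attribute holding a tibble
#'   of removed rows (`variant_id`, `reason`) and an `"actions"` attribute
#'   listing normalisations applied (e.g. uppercasing).
#' @export
validate_summary_stats <- function(data) {
  data <- as_tibble(data)
  actions <- character()

  for (col in setdiff(MANDATORY_COLS, names(data))) {
    abort(glue::glue("missing mandatory column: {col}"),
          class = "metabomr_format_error")
  }
  had_lower <- any(grepl("[a-z]", c(data$effect_allele, data$other_allele)))
  data$effect_allele <- toupper(data$effect_allele)
  data$other_allele <- toupper(data$other_allele)
  if (had_lower) actions <- c(actions, "uppercased alleles")

  reason <- rep(NA_character_, nrow(data))
  flag <- function(bad, why) {
    bad[is.na(bad)] <- TRUE
    ifelse(is.na(reason) & bad, why, reason)
  }
  reason <- flag(!data$effect_allele %in% VALID_BASES |
                   !data$other_allele %in% VALID_BASES, "invalid allele")
  reason <- flag(data$effect_allele == data$other_allele, "identical alleles")
  reason <- flag(!is.finite(data$beta), "unparsable beta")
  reason <- flag(!is.finite(data$se) | data$se <= 0, "nonpositive se")
  reason <- flag(!is.finite(data$pval) | data$pval <= 0 | data$pval > 1,
                 "pval outside (0,1]")
  if ("eaf" %in% names(data)) {
    bad_eaf <- !is.na(data$eaf) & (data$eaf < 0 | data$eaf > 1)
    reason <- ifelse(is.na(reason) & bad_eaf, "eaf outside [0,1]", reason)
  }
  if ("pos" %in% names(data)) {
    bad_pos <- !is.na(data$pos) & data$pos < 1
    reason <- ifelse(is.na(reason) & bad_pos, "position < 1", reason)
  }
  dup <- duplicated(data$variant_id)
  reason <- ifelse(is.na(reason) & dup, "duplicate variant_id", reason)

  rejected <- tibble(variant_id = data$variant_id[!is.na(reason)],
                     reason = reason[!is.na(reason)])
  out <- data[is.na(reason), , drop = FALSE]
  attr(out, "rejected") <- rejected
  attr(out, "actions") <- actions
  out
}

#' Read GWAS summary statistics from a delimited file
#'
#' Reads a tab-separated (or otherwise delimited) summary-statistics file,
#' renames columns to the canonical schema via a [sumstats_dialect()], and
#' validates every row. Invalid rows are dropped and reported through the
#' `"rejected"` attribute of the result.
#'
#' @param path Path to a delimited text file with a header row.
#' @param dialect Column mapping from [sumstats_dialect()].
#' @param trait_id,trait_label Identifier and human-readable label stored as
#'   attributes on the returned table.
#' @param trait_type `"continuous"` (per-SD betas) or `"binary"` (log-odds).
#' @param delim Field delimiter, tab by default.
#' @return A tibble of validated variant associations with attributes
#'   `trait_id`, `trait_label`, `trait_type`, `rejected`, `actions`.
#' @seealso [write_summary_stats()], [validate_summary_stats()]
#' @export
read_summary_stats <- function(path, dialect = sumstats_dialect(),
                               trait_id = NULL, trait_label = trait_id,
                               trait_type = c("continuous", "binary"),
                               delim = "\t") {
  trait_type <- arg_match(trait_type)
  if (!file.exists(path)) {
    abort(glue::glue("summary-statistics file not found: {path}"),
          class = "metabomr_config_error")
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  for (col in MANDATORY_COLS) {
    if (!dialect[[col]] %in% names(raw)) {
      abort(glue::glue("missing mandatory column: {dialect[[col]]} (for {col})"),
            class = "metabomr_format_error")
    }
  }
  present <- dialect[dialect %in% names(raw)]
  data <- raw[, unname(present), drop = FALSE]
  names(data) <- names(present)
  num_cols <- intersect(c("pos", "eaf", "beta", "se", "pval",
                          "n", "n_case", "n_control"), names(data))
  for (col in num_cols) data[[col]] <- suppressWarnings(as.numeric(data[[col]]))
  data$variant_id <- as.character(data$variant_id)
  if ("chrom" %in% names(data)) data$chrom <- as.character(data$chrom)

  out <- validate_summary_stats(data)
  attr(out, "trait_id") <- trait_id %||% tools::file_path_sans_ext(basename(path))
  attr(out, "trait_label") <- trait_label %||% attr(out, "trait_id")
  attr(out, "trait_type") <- trait_type
  out
}

#' Write summary statistics as TSV
#'
#' @param data A tibble of variant associations.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(data, path) {
  readr::write_tsv(as_tibble(data), path, progress = FALSE)
  invisible(path)
}

#' Read an LD matrix of squared correlations
#'
#' The file format is a square tab-separated matrix with variant ids as both
#' the header row and the first column. The matrix must be symmetric with a
#' unit diagonal and entries in \[0, 1\].
#'
#' @param path Path to the TSV file.
#' @return A symmetric numeric matrix with variant ids as dimnames.
#' @export
read_ld_matrix <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  dimnames(m) <- list(ids, colnames(raw)[-1])
  validate_ld_matrix(m)
}

#' @rdname read_ld_matrix
#' @param r2 A square symmetric matrix of squared correlations with dimnames.
#' @export
write_ld_matrix <- function(r2, path) {
  df <- as_tibble(r2, rownames = "variant_id")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

validate_ld_matrix <- function(r2) {
  if (!is.matrix(r2) || nrow(r2) != ncol(r2)) {
    abort("LD matrix must be square", class = "metabomr_format_error")
  }
  if (is.null(rownames(r2)) || !identical(rownames(r2), colnames(r2))) {
    abort("LD matrix must carry matching variant-id dimnames",
          class = "metabomr_format_error")
  }
  if (any(r2 < 0 | r2 > 1, na.rm = TRUE)) {
    abort("LD r-squared entries must lie in [0,1]",
          class = "metabomr_format_error")
  }
  if (max(abs(r2 - t(r2))) > 1e-8) {
    abort("LD matrix must be symmetric", class = "metabomr_format_error")
  }
  if (max(abs(diag(r2) - 1)) > 1e-8) {
    abort("LD matrix diagonal must equal 1", class = "metabomr_format_error")
  }
  r2
}
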