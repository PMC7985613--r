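#' Read condition codelists
#'
#' Codelists map opaque clinical codes to named conditions. Two kinds are
#' distinguished: `morbidity` (diagnosis/symptom codes) and `prescription`
#' (drug codes, e.g. oral corticosteroids or antibiotics). The file format is
#' a UTF-8 CSV with header `list_name,kind,code`. Codes carry no terminology
#' semantics here; synthetic data and codelists simply share a namespace.
#'
#' Duplicate (list, code) rows are collapsed to one with a warning, so a
#' reloaded list always has set semantics.
#'
#' @param path Path to a codelist CSV.
#' @return A tibble with columns `list_name`, `kind`, `code`, one row per
#'   distinct code, grouped-sorted by list.
#' @export
read_codelists <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", stringsAsFactors = FALSE)
  as_codelists(df)
}

#' Validate a codelist table
#'
#' @param df A data frame with columns `list_name`, `kind`, `code`.
#' @return A validated tibble of codelists.
#' @export
as_codelists <- function(df) {
  needed <- c("list_name", "kind", "code")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("codelist table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- tibble::as_tibble(df)[needed]
  if (nrow(df) == 0) {
    stop("codelist table is empty", call. = FALSE)
  }
  bad_kind <- setdiff(unique(df$kind), c("morbidity", "prescription"))
  if (length(bad_kind)) {
    stop("unknown codelist kind(s): ", paste(bad_kind, collapse = ", "),
         "; expected 'morbidity' or 'prescription'", call. = FALSE)
  }
  dup <- duplicated(df[c("list_name", "code")])
  if (any(dup)) {
    warning(sum(dup), " duplicate code row(s) collapsed in codelists: ",
            paste(unique(df$list_name[dup]), collapse = ", "), call. = FALSE)
    df <- df[!dup, ]
  }
  mixed <- dplyr::summarise(dplyr::group_by(df, .data$list_name),
                            n_kind = dplyr::n_distinct(.data$kind))
  if (any(mixed$n_kind > 1)) {
    stop("codelist(s) declared with more than one kind: ",
         paste(mixed$list_name[mixed$n_kind > 1], collapse = ", "),
         call. = FALSE)
  }
  dplyr::arrange(df, .data$list_name, .data$code)
}

#' Write codelists to CSV
#'
#' @param codelists A codelist tibble as returned by [read_codelists()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_codelists <- function(codelists, path) {
  utils::write.csv(as_codelists(codelists), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract one codelist's codes
#'
#' @param codelists A codelist tibble.
#' @param name List name to extract.
#' @return Character vector of codes.
#' @export
codelist_codes <- function(codelists, name) {
  codes <- codelists$code[codelists$list_name == name]
  if (length(codes) == 0) {
    stop("codelist '", name, "' is empty or not defined", call. = FALSE)
  }
  codes
}
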