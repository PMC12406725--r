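#' Built-in gene-symbol alias map
#'
#' A small alias table used to canonicalize gene identifiers before any
#' cross-table join. Proteomics outputs, interaction databases and
#' expression tables frequently disagree on which synonym of a gene symbol
#' they carry (the classic case in macrophage secretome work being
#' TGFBI vs BIGH3), so every reader funnels identifiers through one shared
#' map. The built-in map covers only symbols that recur in this problem
#' domain; users extend it via the `aliases` argument of the readers.
#'
#' @return A named character vector mapping alias to canonical symbol.
#'   Canonical symbols map to themselves so lookups are total.
#' @examples
#' default_aliases()[["TGFBI"]]
#' @export
default_aliases <- function() {
  c(
    TGFBI  = "BIGH3",
    BIGH3  = "BIGH3",
    MRP14  = "S100A9",
    S100A9 = "S100A9",
    LYZ    = "LYZ"
  )
}

#' Canonicalize a gene identifier
#'
#' Uppercases, strips surrounding whitespace, and resolves the result
#' through an alias map. Applied identically by every reader, so all
#' downstream joins operate on one identifier space. Idempotent:
#' `harmonize_id(harmonize_id(x)) == harmonize_id(x)`.
#'
#' @param raw Character vector of raw identifiers. Empty strings are an
#'   error.
#' @param aliases Named character vector mapping alias to canonical symbol
#'   (default [default_aliases()]). Must be acyclic in the sense that
#'   canonical symbols map to themselves; a map whose targets are not
#'   themselves canonical is rejected.
#' @return Character vector of canonical identifiers, same length as `raw`.
#' @examples
#' harmonize_id("TGFBI")           # "BIGH3"
#' harmonize_id(" s100a9 ")        # "S100A9"
#' @export
harmonize_id <- function(raw, aliases = default_aliases()) {
  if (!is.character(raw)) {
    stop("`raw` must be a character vector", call. = FALSE)
  }
  out <- toupper(trimws(raw))
  if (any(is.na(out) | out == "")) {
    stop("empty identifier(s) at position(s): ",
         paste(which(is.na(out) | out == ""), collapse = ", "),
         call. = FALSE)
  }
  if (length(aliases)) {
    check_alias_map(aliases)
    hit <- match(out, names(aliases))
    out[!is.na(hit)] <- unname(aliases[hit[!is.na(hit)]])
  }
  out
}

# Alias map must be stable under one application: every target symbol that
# also appears as a key must map to itself, otherwise harmonization would
# not be idempotent.
check_alias_map <- function(aliases) {
  if (is.null(names(aliases)) || any(names(aliases) == "")) {
    stop("alias map must be a fully named character vector", call. = FALSE)
  }
  targets <- unname(aliases)
  keyed <- targets[targets %in% names(aliases)]
  bad <- keyed[aliases[keyed] != keyed]
  if (length(bad)) {
    stop("alias map is not canonical-stable for: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  invisible(aliases)
}
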