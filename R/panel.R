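#' Construct an analyte panel
#'
#' An analyte panel is the roster of analytes over which every matrix in the
#' pipeline is indexed, together with an alias table mapping synonymous names
#' (for instance the interleukin-numbered forms of chemokines) onto a single
#' canonical spelling. Canonical naming follows the systematic chemokine
#' nomenclature where two forms are in common use (CXCL8 rather than IL-8,
#' CXCL10 rather than IP-10, CCL2 rather than MCP-1, and so on), since that
#' is the form downstream results are reported in.
#'
#' @param analytes Character vector of canonical analyte names.
#' @param aliases Named character vector mapping alias -> canonical name.
#'   Canonical names resolve to themselves whether or not they appear here.
#' @param excluded Optional character vector of analytes flagged as excluded
#'   by the near-zero-variance filter (populated downstream; must be a subset
#'   of `analytes`).
#'
#' @return An object of class `ontokine_panel`.
#' @export
#' @examples
#' p <- analyte_panel(c("IL-6", "CXCL10"), aliases = c("IP-10" = "CXCL10"))
#' resolve_analytes(p, c("IP-10", "IL-6"))
analyte_panel <- function(analytes, aliases = character(), excluded = character()) {
  analytes <- as.character(analytes)
  if (length(aliases)) {
    if (is.null(names(aliases)) || any(!nzchar(names(aliases)))) {
      abort("`aliases` must be a named character vector (alias -> canonical).")
    }
    bad <- setdiff(unname(aliases), analytes)
    if (length(bad)) {
      abort(paste0("Alias targets not in panel: ", paste(bad, collapse = ", ")))
    }
  }
  # resolve each entry so that two spellings of one analyte are caught
  canon <- ifelse(analytes %in% names(aliases), unname(aliases[analytes]), analytes)
  dup <- unique(canon[duplicated(canon)])
  if (length(dup)) {
    abort(paste0(
      "Duplicate analyte(s) after alias resolution: ",
      paste(dup, collapse = ", ")
    ))
  }
  bad_ex <- setdiff(excluded, analytes)
  if (length(bad_ex)) {
    abort(paste0("`excluded` not in panel: ", paste(bad_ex, collapse = ", ")))
  }
  structure(
    list(
      analytes = analytes,
      aliases = aliases,
      excluded = as.character(excluded)
    ),
    class = "ontokine_panel"
  )
}

#' The default 41-analyte multiplex panel
#'
#' The roster of a premixed 41-plex human cytokine/chemokine magnetic bead
#' kit, under canonical chemokine nomenclature, with the vendor's alternate
#' spellings provided as aliases.
#'
#' @return An `ontokine_panel` with 41 analytes.
#' @export
#' @examples
#' length(default_panel()$analytes)
default_panel <- function() {
  analytes <- c(
    "sCD40L", "EGF", "FGF-2", "Flt-3L", "CX3CL1", "G-CSF", "GM-CSF",
    "CXCL1", "IFN-a2", "IFN-g", "IL-1a", "IL-1b", "IL-1RA", "IL-2",
    "IL-3", "IL-4", "IL-5", "IL-6", "IL-7", "CXCL8", "IL-9", "IL-10",
    "IL-12p40", "IL-12p70", "IL-13", "IL-15", "IL-17A", "CXCL10",
    "CCL2", "CCL7", "CCL22", "CCL3", "CCL4", "PDGF-AB/BB", "CCL5",
    "TGF-a", "TNF-a", "TNF-b", "VEGF", "CCL11", "PDGF-AA"
  )
  aliases <- c(
    "IL-8"        = "CXCL8",
    "IP-10"       = "CXCL10",
    "MCP-1"       = "CCL2",
    "MCP-3"       = "CCL7",
    "MDC"         = "CCL22",
    "MIP-1a"      = "CCL3",
    "MIP-1alpha"  = "CCL3",
    "MIP-1b"      = "CCL4",
    "MIP-1beta"   = "CCL4",
    "RANTES"      = "CCL5",
    "Eotaxin"     = "CCL11",
    "Fractalkine" = "CX3CL1",
    "GRO"         = "CXCL1",
    "Flt-3 ligand" = "Flt-3L",
    "IFN-alpha2"  = "IFN-a2",
    "IFN-gamma"   = "IFN-g",
    "TNF-alpha"   = "TNF-a",
    "TNF-beta"    = "TNF-b",
    "TGF-alpha"   = "TGF-a",
    "IL-12 (p40)" = "IL-12p40",
    "IL-12 (p70)" = "IL-12p70"
  )
  analyte_panel(analytes, aliases)
}

#' Load an analyte panel from file
#'
#' Reads a panel definition from CSV (columns `analyte` and optionally
#' `alias`, with `alias` holding a `;`-separated list of synonyms) or JSON
#' (object with fields `analytes` and optional `aliases`).
#'
#' @param path Path to a `.csv` or `.json` panel file.
#' @return An `ontokine_panel`.
#' @export
load_panel <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    aliases <- unlist(x$aliases %||% character())
    return(analyte_panel(x$analytes, aliases = aliases))
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"analyte" %in% names(df)) abort("Panel CSV needs an `analyte` column.")
  aliases <- character()
  if ("alias" %in% names(df)) {
    for (i in seq_len(nrow(df))) {
      al <- df$alias[i]
      if (is.na(al) || !nzchar(al)) next
      for (a in trimws(strsplit(al, ";", fixed = TRUE)[[1]])) {
        aliases[a] <- df$analyte[i]
      }
    }
  }
  analyte_panel(df$analyte, aliases = aliases)
}

#' Resolve analyte names against a panel
#'
#' Maps a vector of analyte names (canonical, alias, or the combined
#' `"Alias (Canonical)"` vendor form) onto canonical panel names. Resolution
#' is idempotent: canonical names resolve to themselves.
#'
#' @param panel An `ontokine_panel`.
#' @param x Character vector of names to resolve.
#' @param error_on_unknown Error (default) or return `NA` for unknown names.
#' @return Character vector of canonical names.
#' @export
resolve_analytes <- function(panel, x, error_on_unknown = TRUE) {
  stopifnot(inherits(panel, "ontokine_panel"))
  x0 <- as.character(x)
  x <- trimws(x0)
  # vendor exports often write "IP-10 (CXCL10)"; accept either half
  par_inner <- sub("^.*\\(([^)]*)\\)\\s*$", "\\1", x)
  par_outer <- trimws(sub("\\s*\\([^)]*\\)\\s*$", "", x))
  lookup <- function(nm) {
    ifelse(nm %in% panel$analytes, nm,
      ifelse(nm %in% names(panel$aliases), unname(panel$aliases[nm]), NA_character_)
    )
  }
  out <- lookup(x)
  # combined forms: prefer whichever component resolves
  miss <- is.na(out) & par_inner != x
  out[miss] <- lookup(par_inner[miss])
  miss <- is.na(out) & par_outer != x
  out[miss] <- lookup(par_outer[miss])
  if (error_on_unknown && anyNA(out)) {
    abort(paste0(
      "Unknown analyte name(s): ",
      paste(unique(x0[is.na(out)]), collapse = ", ")
    ))
  }
  out
}

#' @export
print.ontokine_panel <- function(x, ...) {
  cat("<ontokine_panel> ", length(x$analytes), " analytes",
    if (length(x$excluded)) paste0(" (", length(x$excluded), " excluded)"),
    "\n",
    sep = ""
  )
  cat(strwrap(paste(x$analytes, collapse = ", "), width = 76, prefix = "  "),
    sep = "\n"
  )
  invisible(x)
}

#' Analytes retained after exclusion
#' @param panel An `ontokine_panel`.
#' @return Character vector of analytes not flagged excluded.
#' @export
retained_analytes <- function(panel) {
  setdiff(panel$analytes, panel$excluded)
}
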