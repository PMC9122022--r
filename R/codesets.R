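#' Clinical code sets
#'
#' A code-set configuration maps each category of clinical concept used by
#' the cohort selection, the case-identification algorithms, the exclusion
#' rules and the imaging-proximity checks to a set of Read-style code
#' strings. Recognised categories are:
#' `knee_oa`, `knee_pain`, `imaging`, `exclusion_ra`, `exclusion_gout`,
#' `exclusion_pseudogout`, `exclusion_psa`, `tkr`.
#'
#' The default knee-pain set contains the five published Read codes (knee
#' pain 1M10.00; anterior knee pain 1M12.00, N094W00; knee joint pain
#' N094611; arthralgia of knee N094M00). All other default sets are
#' SYNTHETIC placeholders: the authoritative lists were never published, so
#' every category is user-overridable through a YAML configuration file.
#'
#' @name codesets
NULL

CODESET_CATEGORIES <- c("knee_oa", "knee_pain", "imaging",
                        "exclusion_ra", "exclusion_gout",
                        "exclusion_pseudogout", "exclusion_psa", "tkr")

RHEUMATIC_EXCLUSION_CATEGORIES <- c("exclusion_ra", "exclusion_gout",
                                    "exclusion_pseudogout", "exclusion_psa")

#' Default code-set configuration
#'
#' @return a named list of character vectors with class `oa_codesets`.
#'   Only `knee_pain` is authoritative; the rest are synthetic placeholders
#'   (see [codesets]).
#' @export
default_codesets <- function() {
  cs <- list(
    # published knee-pain Read codes
    knee_pain = c("1M10.00", "1M12.00", "N094W00", "N094611", "N094M00"),
    # synthetic placeholders below (authoritative lists unpublished)
    knee_oa   = c("N05z600", "N05zL00", "N051900"),
    imaging   = c("53B..00", "585f.00"),
    exclusion_ra         = c("N040.00", "N040100"),
    exclusion_gout       = c("C34..00", "C340.00"),
    exclusion_pseudogout = c("N023.00"),
    exclusion_psa        = c("M160000"),
    tkr       = c("7K30500", "7K30y00")
  )
  validate_codesets(cs)
}

#' Validate a code-set configuration
#'
#' Checks category names, non-empty codes, and that `knee_oa` and
#' `knee_pain` do not overlap (a code shared between the two index-code
#' categories would make [categorize_code()] ambiguous).
#'
#' @param codesets named list of character vectors.
#' @return the validated configuration, classed `oa_codesets`.
#' @export
validate_codesets <- function(codesets) {
  stopifnot(is.list(codesets), !is.null(names(codesets)))
  unknown <- setdiff(names(codesets), CODESET_CATEGORIES)
  if (length(unknown)) {
    stop("unknown code-set categories: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(codesets)) {
    codes <- as.character(codesets[[nm]])
    if (any(!nzchar(codes))) {
      stop("empty code string in category '", nm, "'", call. = FALSE)
    }
    codesets[[nm]] <- unique(codes)
  }
  both <- intersect(codesets[["knee_oa"]] %||% character(),
                    codesets[["knee_pain"]] %||% character())
  if (length(both)) {
    stop("codes present in both knee_oa and knee_pain: ",
         paste(both, collapse = ", "), call. = FALSE)
  }
  structure(codesets, class = "oa_codesets")
}

#' Read / write code sets as YAML
#'
#' @param path path to a YAML file mapping category name to a list of codes.
#' @return `read_codesets()` returns a validated `oa_codesets` object.
#' @export
read_codesets <- function(path) {
  validate_codesets(yaml::read_yaml(path))
}

#' @rdname read_codesets
#' @param codesets an `oa_codesets` object.
#' @export
write_codesets <- function(codesets, path) {
  yaml::write_yaml(lapply(unclass(codesets), as.list), path)
  invisible(path)
}

#' Categorize a clinical code
#'
#' Looks up which category a code belongs to. Vectorised over `code`.
#'
#' @param code character vector of code strings.
#' @param codesets an `oa_codesets` configuration.
#' @return character vector of category names, `NA` for codes in no set.
#' @export
categorize_code <- function(code, codesets) {
  lut <- stats::setNames(
    rep(names(codesets), lengths(codesets)),
    unlist(codesets, use.names = FALSE)
  )
  unname(lut[as.character(code)])
}
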