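#' @import data.table
#' @importFrom stats quantile rbinom rgeom rpois runif setNames
#' @importFrom utils read.csv write.csv
NULL

# Closed vocabulary of condition groupings in the neurodisability code list.
.np_categories <- c(
  "neurodevelopmental", "complex neurologic", "inherited/congenital",
  "high-risk brain", "visual impairment", "hearing impairment",
  "motor function", "perinatal"
)

#' Condition categories of the neurodisability code list
#'
#' The eight top-level groupings into which code-list subgroups are
#' organised (neurodevelopmental conditions, complex neurologic conditions,
#' inherited/congenital conditions, high-risk conditions affecting the
#' brain, visual impairment, hearing impairment, impairment of motor
#' function, perinatal conditions).
#'
#' @return character vector of category labels.
#' @export
codelist_categories <- function() .np_categories

#' Normalise an ICD-10 or OPCS-4 code
#'
#' Hospital episode data store codes undotted ("F840"); code lists and user
#' input are often dotted ("F84.0"). Normalisation strips whitespace and
#' dots and upper-cases, then validates against the system's shape:
#' ICD-10 is a letter, two digits, then up to two alphanumerics (3-5
#' characters); OPCS-4 is a letter, two digits, then up to one alphanumeric
#' (3-4 characters). Over-long codes (fifth-character dialects and beyond)
#' are truncated to the maximum length with a warning.
#'
#' @param x character vector of raw codes.
#' @param system `"ICD10"` or `"OPCS4"`.
#' @return character vector of normalised codes.
#' @examples
#' normalize_code("f84.0", "ICD10")   # "F840"
#' normalize_code(" Q05.9", "ICD10")  # "Q059"
#' @export
normalize_code <- function(x, system = c("ICD10", "OPCS4")) {
  system <- match.arg(system)
  out <- toupper(gsub("[.[:space:]]", "", as.character(x)))
  if (any(!nzchar(out) | is.na(out)))
    stop("empty code after normalization at position(s): ",
         paste(which(!nzchar(out) | is.na(out)), collapse = ", "))
  maxlen <- if (system == "ICD10") 5L else 4L
  long <- nchar(out) > maxlen
  if (any(long)) {
    warning(sprintf("truncating %d %s code(s) longer than %d characters: %s",
                    sum(long), system, maxlen,
                    paste(utils::head(out[long], 5L), collapse = ", ")))
    out[long] <- substr(out[long], 1L, maxlen)
  }
  pat <- if (system == "ICD10") "^[A-Z][0-9]{2}[A-Z0-9]{0,2}$"
         else                   "^[A-Z][0-9]{2}[A-Z0-9]{0,1}$"
  bad <- !grepl(pat, out)
  if (any(bad))
    stop(sprintf("malformed %s code(s): %s", system,
                 paste(unique(out[bad]), collapse = ", ")))
  out
}

# internal constructor: validate and classify a code-list data.frame
.as_codelist <- function(df, version = "unversioned", source = "unknown") {
  req <- c("code", "system", "subgroup", "category", "match_mode")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("code list is missing column(s): ", paste(missing_cols, collapse = ", "))
  dt <- as.data.table(df)[, req, with = FALSE]
  for (j in req) set(dt, j = j, value = trimws(as.character(dt[[j]])))
  dt[match_mode == "", match_mode := "prefix"]

  bad_sys <- setdiff(unique(dt$system), c("ICD10", "OPCS4"))
  if (length(bad_sys)) stop("unknown code system: ", paste(bad_sys, collapse = ", "))
  bad_cat <- !dt$category %in% .np_categories
  if (any(bad_cat))
    stop("unknown category in row(s) ", paste(which(bad_cat), collapse = ", "),
         ": ", paste(unique(dt$category[bad_cat]), collapse = ", "))
  bad_mode <- !dt$match_mode %in% c("prefix", "exact")
  if (any(bad_mode))
    stop("unknown match_mode in row(s) ", paste(which(bad_mode), collapse = ", "))

  # a subgroup must map to exactly one category
  multi <- dt[, uniqueN(category), by = subgroup][V1 > 1L, subgroup]
  if (length(multi))
    stop("subgroup(s) mapped to more than one category: ",
         paste(multi, collapse = ", "))

  for (s in c("ICD10", "OPCS4")) {
    idx <- dt$system == s
    if (any(idx)) set(dt, which(idx), "code", normalize_code(dt$code[idx], s))
  }

  ndup <- nrow(dt) - nrow(unique(dt))
  if (ndup > 0L) {
    .np_msg(sprintf("dropped %d duplicate code-list row(s)", ndup))
    dt <- unique(dt)
  }

  # prefix-redundancy reduction: within one system and subgroup, a code that
  # extends a shorter prefix-mode code is unreachable and is collapsed
  dt[, .drop := FALSE]
  pref <- dt[match_mode == "prefix"]
  if (nrow(pref)) {
    for (i in seq_len(nrow(dt))) {
      anc <- pref[system == dt$system[i] & subgroup == dt$subgroup[i] &
                    nchar(code) < nchar(dt$code[i]) &
                    code == substr(dt$code[i], 1L, nchar(code))]
      if (nrow(anc)) set(dt, i, ".drop", TRUE)
    }
  }
  if (any(dt$.drop)) {
    .np_msg(sprintf("collapsed %d redundant descendant code(s) into prefix entries",
                    sum(dt$.drop)))
    dt <- dt[.drop == FALSE]
  }
  dt[, .drop := NULL]

  if (anyDuplicated(dt[, .(code, system)]))
    stop("duplicate (code, system) pairs map to different subgroups: ",
         paste(dt[duplicated(dt[, .(code, system)]), code], collapse = ", "))

  out <- setDF(dt)
  attr(out, "version") <- version
  attr(out, "source") <- source
  class(out) <- c("neuro_codelist", "data.frame")
  out
}

#' Load a neurodisability code list from CSV
#'
#' The CSV must carry columns `code,system,subgroup,category,match_mode`
#' (`notes` optional). Codes are normalised; exact duplicate rows are
#' dropped and, within a system and subgroup, codes that extend a shorter
#' prefix-matching entry are collapsed into it (both logged). Rows with a
#' category outside [codelist_categories()], an unknown system, or a
#' malformed code are rejected with the offending value named.
#'
#' @param path path to the CSV file.
#' @param version,source free-text provenance labels stored as attributes;
#'   `version` defaults to the file name.
#' @return a `neuro_codelist`: a data.frame of normalised entries.
#' @seealso [example_codelist()], [match_code()]
#' @export
load_codelist <- function(path, version = basename(path), source = path) {
  if (!file.exists(path)) stop("code-list file not found: ", path)
  df <- read.csv(path, colClasses = "character", check.names = TRUE)
  .as_codelist(df, version = version, source = source)
}

#' @export
print.neuro_codelist <- function(x, ...) {
  cat(sprintf("<neuro_codelist> %d entries, %d subgroups, %d categories (version: %s)\n",
              nrow(x), length(unique(x$subgroup)), length(unique(x$category)),
              attr(x, "version")))
  tab <- table(x$category)
  for (nm in names(tab)) cat(sprintf("  %-22s %d entries\n", nm, tab[[nm]]))
  invisible(x)
}

#' Match observed clinical codes against a code list
#'
#' A prefix-mode entry matches an observed code when the entry's code is a
#' (possibly equal) prefix of it; an exact-mode entry requires equality.
#' The result for each observed code is the union of subgroups over all
#' matching entries; an empty set is a valid no-match outcome. One matching
#' path serves admission diagnoses, procedures and causes of death.
#'
#' @param observed character vector of normalised codes (see
#'   [normalize_code()]).
#' @param system `"ICD10"` or `"OPCS4"`; which entries to match against.
#' @param codelist a `neuro_codelist`.
#' @return a list, one character vector of subgroup labels per observed
#'   code (possibly empty).
#' @examples
#' cl <- example_codelist()
#' match_code("F840", "ICD10", cl)
#' @export
match_code <- function(observed, system = c("ICD10", "OPCS4"), codelist) {
  system <- match.arg(system)
  stopifnot(inherits(codelist, "neuro_codelist"))
  if (!length(observed)) return(list())
  entries <- as.data.table(codelist)[system, on = "system"]
  if (!nrow(entries) || all(is.na(entries$code)))
    return(rep(list(character(0)), length(observed)))
  lens <- sort(unique(nchar(entries$code)))
  obs <- data.table(idx = seq_along(observed), obs = observed)
  # candidate keys: every leading substring of the observed code at an
  # entry length (sorted-prefix lookup; the brute-force scan is the oracle)
  cand <- rbindlist(lapply(lens, function(L)
    obs[nchar(obs) >= L, .(idx, obs, key = substr(obs, 1L, L))]))
  hit <- entries[cand, on = .(code = key), nomatch = NULL,
                 .(idx, obs = i.obs, code, subgroup, match_mode)]
  hit <- hit[match_mode == "prefix" | code == obs]
  out <- rep(list(character(0)), length(observed))
  if (nrow(hit)) {
    agg <- hit[, .(subgroups = list(sort(unique(subgroup)))), by = idx]
    out[agg$idx] <- agg$subgroups
  }
  out
}

#' Illustrative neurodisability code list
#'
#' Builds the code list shipped with the package: a re-derivation of the
#' published subgroup taxonomy using representative ICD-10 chapters (e.g.
#' F70--F79 learning disability, F80--F83 developmental disorders, F84
#' autistic spectrum disorders, G80 cerebral palsy, G40--G41 epilepsy,
#' Q90/Q91 trisomies, Q00--Q07 CNS anomalies, P07 extreme
#' prematurity/low birth weight) and a few OPCS-4 procedure entries
#' (cochlear implantation, CSF shunt). It is illustrative, not the
#' clinically curated published list, and is intended for synthetic-data
#' analyses and testing.
#'
#' @return a `neuro_codelist`.
#' @export
example_codelist <- function() {
  path <- system.file("extdata", "codelist_illustrative.csv",
                      package = "neurophen", mustWork = TRUE)
  load_codelist(path, version = "illustrative-0.1", source = "neurophen::example_codelist")
}
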