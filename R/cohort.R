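# Cohort data model: typed per-case records, CSV round-trip, validation.

# Canonical column order and types. Mitotic counts are stored per
# reported denominator (50 HPF for the adult Weiss convention, 20 HPF
# for the pediatric Wieneke convention); the two are never rescaled
# into one another implicitly because HPF area and counting protocol
# differ between conventions.
.acn_schema <- list(
  case_id                = "character",
  age_months             = "numeric",
  sex                    = "character",   # "M" / "F"
  laterality             = "character",   # "left" / "right"
  stage                  = "character",   # COG stage "I".."IV"
  weight_g               = "numeric",
  size_cm                = "numeric",
  mitoses_50hpf          = "integer",     # mitotic figures per 50 HPF
  mitoses_20hpf          = "integer",     # mitotic figures per 20 HPF
  atypical_mitoses       = "logical",
  necrosis               = "logical",
  vascular_invasion      = "logical",     # venous invasion; single field
  capsular_invasion      = "logical",
  extra_adrenal_extension = "logical",
  vena_cava_invasion     = "logical",
  ki67_percent           = "numeric",
  reticulin              = "character",
  outcome                = "character",   # "CR" / "AWD" / "DOD"
  followup_months        = "numeric"
)

.acn_levels <- list(
  sex        = c("M", "F"),
  laterality = c("left", "right"),
  stage      = c("I", "II", "III", "IV"),
  reticulin  = c("intact", "quantitative", "qualitative", "both"),
  outcome    = c("CR", "AWD", "DOD")
)

.acn_fields <- names(.acn_schema)

#' Construct a single case record
#'
#' Builds a one-row cohort `data.frame` holding the histopathology,
#' clinical and outcome fields used by the scoring rules. Every field
#' not supplied is missing (`NA`). Binary histologic features are
#' tristate logicals (`TRUE`/`FALSE`/`NA`); `reticulin` is one of
#' `"intact"`, `"quantitative"`, `"qualitative"`, `"both"` (the last
#' meaning quantitative and qualitative alterations coexist).
#'
#' Mitotic activity is stored per reporting convention:
#' `mitoses_50hpf` is the count over 50 high-power fields (adult/Weiss
#' convention) and `mitoses_20hpf` the count over 20 HPF (pediatric
#' convention). Cutoffs are only ever compared against the count with
#' the matching denominator.
#'
#' @param case_id Unique case identifier (string).
#' @param age_months Age at diagnosis in months.
#' @param sex `"M"` or `"F"`.
#' @param laterality `"left"` or `"right"`.
#' @param stage Children's Oncology Group stage, `"I"`..`"IV"`.
#' @param weight_g Tumor weight in grams.
#' @param size_cm Greatest tumor dimension in centimeters.
#' @param mitoses_50hpf Mitotic figures counted over 50 HPF.
#' @param mitoses_20hpf Mitotic figures counted over 20 HPF.
#' @param atypical_mitoses,necrosis,vascular_invasion,capsular_invasion
#'   Tristate histologic features. `vascular_invasion` is venous
#'   invasion; the model keeps a single field for both the Wieneke
#'   "venous invasion" item and the reticulin-algorithm criterion.
#' @param extra_adrenal_extension,vena_cava_invasion Tristate features
#'   (extension into periadrenal soft tissue / adjacent organs; tumor
#'   within the vena cava).
#' @param ki67_percent Ki67 proliferative index in percent, 0-100.
#' @param reticulin Reticulin framework status (see Details).
#' @param outcome `"CR"` (complete remission), `"AWD"` (alive with
#'   disease) or `"DOD"` (died of disease).
#' @param followup_months Follow-up time in months.
#' @return A one-row `data.frame` with class `acn_cohort`.
#' @examples
#' acn_case("T1", necrosis = TRUE, reticulin = "quantitative",
#'          mitoses_20hpf = 18, mitoses_50hpf = 40)
#' @export
acn_case <- function(case_id,
                     age_months = NA, sex = NA, laterality = NA,
                     stage = NA, weight_g = NA, size_cm = NA,
                     mitoses_50hpf = NA, mitoses_20hpf = NA,
                     atypical_mitoses = NA, necrosis = NA,
                     vascular_invasion = NA, capsular_invasion = NA,
                     extra_adrenal_extension = NA,
                     vena_cava_invasion = NA, ki67_percent = NA,
                     reticulin = NA, outcome = NA,
                     followup_months = NA) {
  args <- mget(.acn_fields)
  as_cohort(as.data.frame(args, stringsAsFactors = FALSE))
}

#' Coerce a data frame to a cohort
#'
#' Reorders and type-coerces columns to the canonical cohort schema.
#' Columns absent from `x` are created as all-missing; unknown columns
#' are preserved after the canonical ones (so score-panel columns
#' survive coercion).
#'
#' @param x A `data.frame` with at least a `case_id` column.
#' @param provenance Free-text label recording where the cohort came
#'   from; stored as an attribute.
#' @return A `data.frame` of class `acn_cohort`.
#' @export
as_cohort <- function(x, provenance = NULL) {
  stopifnot(is.data.frame(x))
  if (!"case_id" %in% names(x)) {
    stop("schema error: mandatory column 'case_id' is absent",
         call. = FALSE)
  }
  out <- x
  for (f in .acn_fields) {
    v <- if (f %in% names(x)) x[[f]] else rep(NA, nrow(x))
    out[[f]] <- switch(.acn_schema[[f]],
      character = as.character(v),
      numeric   = as.numeric(v),
      integer   = as.integer(v),
      logical   = as.logical(v))
  }
  extra <- setdiff(names(x), .acn_fields)
  out <- out[, c(.acn_fields, extra), drop = FALSE]
  dup <- unique(out$case_id[duplicated(out$case_id)])
  if (length(dup)) {
    stop("validation error: duplicate case_id: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  class(out) <- unique(c("acn_cohort", class(out)))
  if (!is.null(provenance)) attr(out, "provenance") <- provenance
  rownames(out) <- NULL
  out
}

# Parse one character column according to the schema type; cells that
# fail to parse in optional fields become NA.
.parse_col <- function(v, type) {
  v <- as.character(v)
  v[!is.na(v) & trimws(v) == ""] <- NA_character_
  v <- trimws(v)
  switch(type,
    character = v,
    numeric   = suppressWarnings(as.numeric(v)),
    integer   = suppressWarnings(as.integer(v)),
    logical   = c("true" = TRUE, "false" = FALSE)[tolower(v)])
}

#' Read a cohort from CSV
#'
#' The expected dialect is comma-separated UTF-8 with a mandatory
#' header; the empty string encodes missing, booleans are serialized
#' as `"true"`/`"false"`. Cells in optional columns that cannot be
#' parsed to the column's type become missing. Column names may be
#' remapped through `schema_config`.
#'
#' @param path Path to a CSV file.
#' @param schema_config Optional column-name mapping from canonical
#'   field names to the file's column names: either a named character
#'   vector (`c(necrosis = "nec", ...)`) or the path of a key-value
#'   text file with lines `canonical=user_column`.
#' @return An `acn_cohort` data frame.
#' @seealso [write_cohort()], [validate_cohort()]
#' @export
read_cohort <- function(path, schema_config = NULL) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE,
                         na.strings = character(0))
  if (!is.null(schema_config)) {
    map <- if (is.character(schema_config) && is.null(names(schema_config)) &&
               length(schema_config) == 1L) {
      read_schema_config(schema_config)
    } else schema_config
    for (canonical in names(map)) {
      usercol <- map[[canonical]]
      if (usercol %in% names(raw)) {
        names(raw)[names(raw) == usercol] <- canonical
      }
    }
  }
  if (!"case_id" %in% names(raw)) {
    stop("schema error: mandatory column 'case_id' is absent from ",
         path, call. = FALSE)
  }
  parsed <- raw
  for (f in intersect(.acn_fields, names(raw))) {
    parsed[[f]] <- .parse_col(raw[[f]], .acn_schema[[f]])
  }
  as_cohort(parsed, provenance = path)
}

#' Read a schema-config mapping file
#'
#' One mapping per line, `canonical_field=column_in_file`; blank lines
#' and lines starting with `#` are ignored.
#'
#' @param path Path to the key-value text file.
#' @return Named character vector mapping canonical names to user
#'   column names.
#' @export
read_schema_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) {
    stop("schema error: malformed mapping line: ",
         lines[bad][1], call. = FALSE)
  }
  stats::setNames(trimws(vapply(kv, `[[`, "", 2L)),
                  trimws(vapply(kv, `[[`, "", 1L)))
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: logical fields are serialized as
#' `"true"`/`"false"`, missing values as the empty string, so that a
#' read/write round trip reproduces every field including its
#' missingness.
#'
#' @param cohort An `acn_cohort` (or coercible data frame).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- as_cohort(cohort)
  out <- cohort[, .acn_fields, drop = FALSE]
  for (f in .acn_fields) {
    v <- out[[f]]
    s <- if (is.logical(v)) {
      ifelse(is.na(v), "", ifelse(v, "true", "false"))
    } else {
      ifelse(is.na(v), "", as.character(v))
    }
    out[[f]] <- s
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   na = "")
  invisible(path)
}

#' Validate a case or cohort
#'
#' Checks every record against the data-model invariants and returns
#' the findings as a data frame -- one row per violation, naming the
#' case, the field and the violated rule. A structurally well-formed
#' record never raises; an empty result means all invariants hold.
#'
#' Rules checked: enumerated fields take only their legal values;
#' `ki67_percent` lies in \[0, 100\]; counts are non-negative; weight,
#' size, age and follow-up are positive/non-negative; and
#' `followup_months` must be present whenever `outcome` is known.
#'
#' @param cohort An `acn_cohort` or coercible data frame (one or more
#'   rows).
#' @return `data.frame` with columns `case_id`, `field`, `rule`.
#' @export
validate_cohort <- function(cohort) {
  x <- as_cohort(cohort)
  findings <- list()
  note <- function(bad, field, rule) {
    bad <- !is.na(bad) & bad
    if (any(bad)) {
      findings[[length(findings) + 1L]] <<- data.frame(
        case_id = x$case_id[bad], field = field, rule = rule,
        stringsAsFactors = FALSE)
    }
  }
  for (f in names(.acn_levels)) {
    note(!(x[[f]] %in% c(.acn_levels[[f]], NA)), f,
         paste0("must be one of: ",
                paste(.acn_levels[[f]], collapse = ", ")))
  }
  note(x$ki67_percent < 0 | x$ki67_percent > 100, "ki67_percent",
       "must lie in [0, 100]")
  note(x$weight_g <= 0, "weight_g", "must be positive")
  note(x$size_cm <= 0, "size_cm", "must be positive")
  note(x$age_months < 0, "age_months", "must be non-negative")
  note(x$mitoses_50hpf < 0, "mitoses_50hpf", "must be non-negative")
  note(x$mitoses_20hpf < 0, "mitoses_20hpf", "must be non-negative")
  note(x$followup_months < 0, "followup_months",
       "must be non-negative")
  note(!is.na(x$outcome) & is.na(x$followup_months), "followup_months",
       "must be present when outcome is known")
  if (!length(findings)) {
    return(data.frame(case_id = character(0), field = character(0),
                      rule = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, findings)
}

#' @rdname validate_cohort
#' @param case A one-row case record, as from [acn_case()].
#' @export
validate_case <- function(case) validate_cohort(case)

#' Reticulin alteration predicate
#'
#' `TRUE` when the reticulin framework shows any alteration
#' (quantitative, qualitative or both), `FALSE` when intact, `NA` when
#' not assessed.
#'
#' @param reticulin Character vector of reticulin categories.
#' @return Logical vector.
#' @export
reticulin_altered <- function(reticulin) {
  bad <- !(reticulin %in% c(.acn_levels$reticulin, NA))
  if (any(bad)) {
    stop("unknown reticulin category: ",
         paste(unique(reticulin[bad]), collapse = ", "), call. = FALSE)
  }
  ifelse(is.na(reticulin), NA, reticulin != "intact")
}
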