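# Scoring-rule configuration: thresholds are data, not code.

#' Default scoring rules
#'
#' Returns the rule set reproducing the published classification
#' systems: Wieneke thresholds (weight >400 g, size >10.5 cm, >15
#' mitoses/20 HPF), the modified-Wieneke two-step rule (microscopic
#' score >= 3 unfavorable, <= 1 favorable, score 2 resolved by Ki67 >=
#' 15%), and the reticulin-algorithm mitotic cutoffs (>5/50 HPF adult,
#' >15/20 HPF pediatric). All mitotic cutoffs are strict inequalities
#' and are compared only against the count with the matching HPF
#' denominator; set `allow_mitotic_rescale = TRUE` to permit linear
#' rescaling (with a warning) when only the other denominator was
#' reported.
#'
#' The modified-Wieneke step-2 rule is a reconstruction: the five
#' microscopic items and the Ki67 cutoff are fixed by the system's
#' published description, but the exact published trigger band is not
#' restated here, so the band is configuration rather than a constant.
#'
#' @return Nested list of thresholds; see [read_rules()] for the
#'   serialized form.
#' @export
default_rules <- function() {
  list(
    wc = list(weight_g = 400, size_cm = 10.5, mitoses_20hpf = 15),
    mwc = list(unfavorable_min = 3, favorable_max = 1,
               ki67_cutoff = 15),
    ra = list(adult_cutoff = 5, adult_denominator = 50,
              pediatric_cutoff = 15, pediatric_denominator = 20),
    allow_mitotic_rescale = FALSE
  )
}

#' Read / write scoring rules
#'
#' Rules are serialized as a flat key-value text file with dotted
#' keys, e.g. `wc.weight_g=400`. The shipped default is at
#' `system.file("extdata", "default_rules.cfg", package = "acnscore")`.
#'
#' @param path Path to a rules file.
#' @return `read_rules()` returns the nested rules list;
#'   `write_rules()` invisibly returns `path`.
#' @export
read_rules <- function(path) {
  kv <- read_schema_config(path)  # same key=value syntax
  rules <- default_rules()
  for (key in names(kv)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    val <- kv[[key]]
    val <- if (tolower(val) %in% c("true", "false")) {
      tolower(val) == "true"
    } else as.numeric(val)
    if (length(parts) == 1L) {
      rules[[parts]] <- val
    } else if (length(parts) == 2L) {
      rules[[parts[1]]][[parts[2]]] <- val
    } else {
      stop("malformed rules key: ", key, call. = FALSE)
    }
  }
  rules
}

#' @rdname read_rules
#' @param rules A rules list, as from [default_rules()].
#' @export
write_rules <- function(rules, path) {
  lines <- character(0)
  for (top in names(rules)) {
    if (is.list(rules[[top]])) {
      for (sub in names(rules[[top]])) {
        lines <- c(lines,
                   paste0(top, ".", sub, "=",
                          tolower(as.character(rules[[top]][[sub]]))))
      }
    } else {
      lines <- c(lines,
                 paste0(top, "=", tolower(as.character(rules[[top]]))))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
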