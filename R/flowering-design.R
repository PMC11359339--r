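#' The candidate flowering-model grid
#'
#' The nine candidate predictor sets compared for the first-flowering-day
#' regression. Every candidate contains the cultivar indicator `CV`; the
#' thermal covariates are `BB` (GDD at 5% budbreak), `DD` (GDD on 1 Sep),
#' `CU` (chilling hours on 1 Sep) and `DL` (daylength on 1 Sep).
#'
#' @return Tibble with columns `label` and `terms` (list column of predictor
#'   character vectors).
#' @export
#' @examples
#' candidate_specs()
candidate_specs <- function() {
  labels <- c("CV.DL", "CV.DD", "CV.BB", "CV.CU", "CV.BB.DD", "CV.BB.CU",
              "CV.BB.DL", "CV.DD.DL", "CV.CU.DL")
  tibble::tibble(
    label = labels,
    terms = lapply(strsplit(labels, ".", fixed = TRUE), identity)
  )
}

#' Build a flowering-model design (formula) from a candidate label
#'
#' For `interactions = "full"` the design contains all main effects and all
#' interactions among the candidate's predictors (the full factorial
#' expansion, e.g. `CV*BB*DD`). For `interactions = "refined"` an explicit
#' term vector must be supplied (as produced by stepwise refinement).
#' Optional `extra` terms (e.g. `row`, `bay`) are added as main effects.
#'
#' @param records Data frame holding the candidate's predictor columns and
#'   the response `first_flower_doy`.
#' @param label Candidate label such as `"CV.BB.DD"`, or a character vector
#'   of predictors.
#' @param interactions `"full"` or `"refined"`.
#' @param terms For `"refined"`: explicit model terms (e.g.
#'   `c("CV", "BB", "DD", "CV:BB", "BB:DD")`).
#' @param extra Additional main-effect terms appended to the formula.
#' @param response Response column name.
#' @return A list of class `flowering_design` with `formula`, `label`,
#'   `terms` (the expanded term labels) and `predictors`.
#' @export
#' @examples
#' rec <- tibble::tibble(CV = 0:1, BB = c(1, 2), first_flower_doy = c(310, 330))
#' build_design(rec, "CV.BB")$terms
build_design <- function(records, label, interactions = c("full", "refined"),
                         terms = NULL, extra = character(),
                         response = "first_flower_doy") {
  interactions <- match.arg(interactions)
  predictors <- if (length(label) == 1 && grepl(".", label, fixed = TRUE)) {
    strsplit(label, ".", fixed = TRUE)[[1]]
  } else {
    as.character(label)
  }
  assert_columns(records, c(predictors, response, extra), "records")

  rhs <- if (interactions == "full") {
    paste(predictors, collapse = " * ")
  } else {
    if (is.null(terms)) {
      abort_phenocast("interactions = 'refined' requires an explicit `terms` vector",
                      "phenocast_config_error")
    }
    paste(terms, collapse = " + ")
  }
  if (length(extra) > 0) rhs <- paste(rhs, "+", paste(extra, collapse = " + "))
  fml <- stats::as.formula(paste(response, "~", rhs))
  expanded <- attr(stats::terms(fml, data = records), "term.labels")
  structure(
    list(formula = fml, label = paste(predictors, collapse = "."),
         terms = c("(Intercept)", expanded), predictors = predictors),
    class = "flowering_design"
  )
}
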