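#' Add an input to an ablation set
#'
#' Post-hoc investigation 1 removes an input by forcing its rate of response
#' to zero: inputs that rise from zero then never appear, and inputs that
#' start at strength are frozen there. The returned set is passed to
#' [run_trials()] (or [simulate_experiment()]) as `ablations`.
#'
#' @param ablations Existing character vector of ablated input names.
#' @param input Input name to add (one of the eight component inputs).
#' @return The extended ablation set.
#' @examples
#' ablate(input = "automated_motor")
#' @export
ablate <- function(ablations = character(), input) {
  if (!input %in% input_names()) stop("unknown input: ", input)
  union(ablations, input)
}

#' Intentional-state trial filter
#'
#' Emulates a task-dependent strategy bias by post-selecting trials: removes
#' pro-saccade trials whose fixation/inhibition strength was high (large
#' MaxVal) and anti-saccade trials whose fixation/inhibition strength was low
#' (small MaxVal), for the voluntary fixation, inhibitory gate and peripheral
#' inhibition inputs. Simulated outcomes are untouched; only the trial set
#' changes, and percentages are recomputed over the survivors.
#'
#' `mode` selects the filtered input: one of the three input names, or
#' `"combined"` to filter on all three at once, or `"off"` for the identity.
#' For the combined filter a pro trial is dropped when *any* of the three
#' caps is large and an anti trial when *any* is small (`rule = "any"`, the
#' default); `rule = "all"` requires all three.
#'
#' @param records Classified trial records with their level columns.
#' @param mode `"off"`, `"combined"`, `"voluntary_fixation"`,
#'   `"inhibitory_gate"` or `"peripheral_inhibition"`.
#' @param rule `"any"` (default) or `"all"`; only used for `"combined"`.
#' @return The surviving records.
#' @export
intentional_state_filter <- function(records,
                                     mode = c("off", "combined",
                                              "voluntary_fixation",
                                              "inhibitory_gate",
                                              "peripheral_inhibition"),
                                     rule = c("any", "all")) {
  mode <- match.arg(mode)
  rule <- match.arg(rule)
  if (mode == "off") return(records)
  cols <- c(voluntary_fixation = "vf_max_level",
            inhibitory_gate = "gate_max_level",
            peripheral_inhibition = "pi_max_level")
  use <- if (mode == "combined") cols else cols[[mode]]
  is_level <- function(lv) {
    m <- vapply(use, function(cl) records[[cl]] == lv, logical(nrow(records)))
    if (length(use) == 1L || rule == "any") {
      rowSums(as.matrix(m)) > 0
    } else {
      rowSums(as.matrix(m)) == length(use)
    }
  }
  drop <- (records$task == "pro" & is_level("large")) |
    (records$task == "anti" & is_level("small"))
  out <- records[!drop, ]
  if (nrow(out) == 0) stop("intentional-state filter removed every trial")
  out
}
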