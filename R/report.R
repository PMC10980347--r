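#' Classify regulators by condition specificity
#'
#' Exact three-way partition of the union of the two retained sets:
#' regulators retained only under stress, only under control, or under
#' both conditions.
#'
#' @param stressSet,controlSet ordered regulator lists, typically from
#'   [thresholdConsensus()] under each condition.
#' @return List with elements `stress_only`, `control_only`, `shared`
#'   (each ordered as in its source set; `shared` follows `stressSet`).
#' @export
classifyConditionSpecific <- function(stressSet, controlSet) {
  stressSet <- unique(as.character(stressSet))
  controlSet <- unique(as.character(controlSet))
  list(stress_only = stressSet[!stressSet %in% controlSet],
       control_only = controlSet[!controlSet %in% stressSet],
       shared = stressSet[stressSet %in% controlSet])
}

#' Filter a regulator list by binding evidence
#'
#' Order-preserving intersection with a binding-evidence gene set
#' (e.g. ChIP-seq-supported binders of the target's promoter). Binding
#' evidence is treated as a binary flag, not a score.
#'
#' @param regulators ordered regulator identifiers.
#' @param bindingSet gene identifiers with binding evidence.
#' @return `regulators` restricted to members of `bindingSet`, order
#'   preserved.
#' @export
filterByBinding <- function(regulators, bindingSet) {
  regulators <- as.character(regulators)
  regulators[regulators %in% as.character(bindingSet)]
}

#' Build the final prioritized regulator report
#'
#' Thresholds both consensus tables ([thresholdConsensus()]), classifies
#' the retained regulators by condition specificity, flags binding
#' evidence, and assigns final priorities by (binding evidence first,
#' then class: stress-specific, shared, control-specific, then stress
#' frequency descending, then identifier).
#'
#' @param stressTable,controlTable [ConsensusResult-class] objects for
#'   the stress and control conditions.
#' @param thresholds numeric of length 2, named `stress` and `control`
#'   (defaults 0.80 and 0.40: the control threshold is lower to absorb
#'   the higher variability of control-condition predictions).
#' @param bindingSet gene identifiers with binding evidence.
#' @return A [RegulatorReport-class] object.
#' @export
buildReport <- function(stressTable, controlTable,
                        thresholds = c(stress = 0.80, control = 0.40),
                        bindingSet = character(0)) {
  if (!is(stressTable, "ConsensusResult") ||
      !is(controlTable, "ConsensusResult"))
    stop("stressTable and controlTable must be ConsensusResult objects")
  if (!all(c("stress", "control") %in% names(thresholds)))
    stop("thresholds must be named 'stress' and 'control'")
  if (any(thresholds < 0 | thresholds > 1))
    stop("thresholds must lie in [0, 1]")

  stressSet <- thresholdConsensus(stressTable, thresholds[["stress"]])
  controlSet <- thresholdConsensus(controlTable, thresholds[["control"]])
  cls <- classifyConditionSpecific(stressSet, controlSet)

  regs <- c(cls$stress_only, cls$shared, cls$control_only)
  classes <- c(rep("stress-specific", length(cls$stress_only)),
               rep("shared", length(cls$shared)),
               rep("control-specific", length(cls$control_only)))
  freqOf <- function(tab, g) {
    f <- tab@table$frequency[match(g, tab@table$regulator)]
    ifelse(is.na(f), 0, f)
  }
  tb <- data.frame(regulator = regs,
                   class = classes,
                   frequency_stress = freqOf(stressTable, regs),
                   frequency_control = freqOf(controlTable, regs),
                   binding_evidence = regs %in% as.character(bindingSet),
                   stringsAsFactors = FALSE)
  classOrder <- match(tb$class,
                      c("stress-specific", "shared", "control-specific"))
  ord <- order(-tb$binding_evidence, classOrder, -tb$frequency_stress,
               tb$regulator)
  tb <- tb[ord, , drop = FALSE]
  tb$final_priority <- seq_len(nrow(tb))
  rownames(tb) <- NULL
  new("RegulatorReport", table = tb,
      thresholds = c(stress = thresholds[["stress"]],
                     control = thresholds[["control"]]))
}
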