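#' Differentiation fate states of a pluripotent GUV
#'
#' A pluripotent GUV carries three dormant apo-metalloenzymes (apo-urease /
#' Ni2+, apo-galactose-oxidase / Cu2+, apo-phospholipase-A2 / Ca2+). Each
#' ionophore addition (A carries Ni2+, B carries Cu2+, C carries Ca2+)
#' activates the matching enzyme, but cross-inhibition between
#' membrane-embedded ionophores makes every subsequent step weaker: the
#' first ionophore sets the primary fate (A: pH rise; B: H2O2 production;
#' C: PLA2 activation and lysis), the second yields only a dampened
#' secondary response (fates A-b, A-c, B-a, B-c), and a third ionophore has
#' no further effect (terminal lock). Lysis (fate C) is absorbing.
#'
#' @param label state label, one of `pluripotent`, `A`, `B`, `C`, `A-b`,
#'   `A-c`, `B-a`, `B-c`.
#' @param history character vector of ionophores applied so far.
#' @param locked whether the state is terminally locked.
#' @return object of class `fate_state`.
#' @export
fate_state <- function(label = "pluripotent", history = character(0),
                       locked = FALSE) {
  valid <- c("pluripotent", "A", "B", "C", "A-b", "A-c", "B-a", "B-c")
  if (!label %in% valid)
    stop_ld("unknown fate label '%s' (valid: %s)", label,
            paste(valid, collapse = ", "))
  if (length(history) > 3L) stop_ld("history length must be <= 3")
  structure(list(label = label, history = history, locked = locked),
            class = "fate_state")
}

#' @export
print.fate_state <- function(x, ...) {
  cat(sprintf("fate_state: %s%s%s\n", x$label,
              if (x$label == "C") " (lysed)" else "",
              if (x$locked) " [terminal-locked]" else ""))
  if (length(x$history))
    cat("  history:", paste(x$history, collapse = " -> "), "\n")
  invisible(x)
}

#' Apply one ionophore addition to a fate state
#'
#' Transition rules: from `pluripotent`, A gives fate `A`, B gives `B`, C
#' gives `C` (lysed, absorbing). Second additions give the dampened fates
#' `A-b`, `A-c`, `B-a`, `B-c`. Any third ionophore — and any input to a
#' lysed GUV — leaves the state unchanged and marks it terminally locked.
#' Re-adding an ionophore already in the history is rejected (not a
#' performed experiment).
#'
#' @param state a [fate_state()].
#' @param ionophore one of `"A"`, `"B"`, `"C"`.
#' @return the new [fate_state()].
#' @export
apply_step <- function(state, ionophore) {
  stopifnot(inherits(state, "fate_state"))
  if (!ionophore %in% c("A", "B", "C"))
    stop_ld("ionophore must be one of A, B, C")
  if (ionophore %in% state$history)
    stop_ld("ionophore %s already applied (history: %s)", ionophore,
            paste(state$history, collapse = ","))
  # absorbing: lysed GUVs and third-step states ignore further input
  if (state$label == "C" || length(state$history) >= 2L)
    return(fate_state(state$label, c(state$history, ionophore),
                      locked = TRUE))
  new_label <- if (state$label == "pluripotent") {
    ionophore
  } else {
    paste0(state$label, "-", tolower(ionophore))
  }
  fate_state(new_label, c(state$history, ionophore), locked = FALSE)
}

#' Terminal fate of an ionophore addition sequence
#'
#' Left-fold of [apply_step()] from the pluripotent state.
#'
#' @param sequence character vector of distinct ionophores from
#'   `{"A","B","C"}` (a permutation prefix).
#' @return the terminal [fate_state()].
#' @export
classify_fate <- function(sequence) {
  Reduce(apply_step, as.character(sequence), init = fate_state())
}

#' Enumerate terminal fates over all ionophore orderings
#'
#' Evaluates all 6 permutations of A, B, C and counts the distinct terminal
#' fates. Both C-first orders collapse to lysis, so the 6 orderings yield 5
#' distinct fates.
#'
#' @return list: `fates` (data frame `order`, `terminal`), `distinct_fates`
#'   (character vector), `n_distinct`.
#' @export
enumerate_fates <- function() {
  perms <- list(c("A", "B", "C"), c("A", "C", "B"), c("B", "A", "C"),
                c("B", "C", "A"), c("C", "A", "B"), c("C", "B", "A"))
  terminal <- vapply(perms, function(p) classify_fate(p)$label, character(1))
  fates <- data.frame(order = vapply(perms, paste, character(1),
                                     collapse = "-"),
                      terminal = terminal)
  list(fates = fates, distinct_fates = sort(unique(terminal)),
       n_distinct = length(unique(terminal)))
}

#' Classify a terminal fate from sensor readouts
#'
#' Maps end-point sensor readouts of one GUV to a fate label: lysis means
#' fate `C`; a high urease-sensor response with modest galactose-oxidase
#' response means the A-first branch (`A-b` if the GUV stayed tight, `A-c`
#' if it became leaky); a high galactose-oxidase response means the B-first
#' branch (`B-a` tight, `B-c` leaky). Readouts matching no rule — including
#' the documented overlap region between `B-a` and `B-c` near the leakage
#' threshold — return `"unclassified"` rather than forcing a call.
#' A lysed flag combined with intact-GUV sensor responses is contradictory
#' and returns `"unclassified"` with a QC note.
#'
#' @param urease_fold urease-sensor fold change over baseline (>= 0).
#' @param gaoa_fold galactose-oxidase-sensor fold change (>= 0).
#' @param leakage_pct dye lost at 20 min (percent, in `[-5, 105]`).
#' @param lysed logical lysis flag.
#' @param thresholds list with `urease_fold`, `gaoa_fold`, `leakage_pct`
#'   cutoffs (defaults 2, 2, 20).
#' @return character fate label with attribute `qc`.
#' @export
classify_from_readouts <- function(urease_fold, gaoa_fold, leakage_pct,
                                   lysed = FALSE,
                                   thresholds = list(urease_fold = 2,
                                                     gaoa_fold = 2,
                                                     leakage_pct = 20)) {
  if (urease_fold < 0 || gaoa_fold < 0)
    stop_ld("fold changes must be >= 0")
  if (leakage_pct < -5 || leakage_pct > 105)
    stop_ld("leakage percentage outside [-5, 105]")
  u_hi <- urease_fold >= thresholds$urease_fold
  g_hi <- gaoa_fold >= thresholds$gaoa_fold
  leaky <- leakage_pct >= thresholds$leakage_pct
  qc <- "ok"
  label <- if (lysed) {
    if (u_hi || g_hi) {
      qc <- "contradictory: lysed GUV with intact-GUV sensor response"
      "unclassified"
    } else "C"
  } else if (u_hi && !g_hi) {
    if (leaky) "A-c" else "A-b"
  } else if (g_hi && !u_hi) {
    if (leaky) "B-c" else "B-a"
  } else "unclassified"
  structure(label, qc = qc)
}
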