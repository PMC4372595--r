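#' @keywords internal
"_PACKAGE"

## Canonical metabolic-state labels, in no particular order.
.suit_states <- c("LEAK", "OXPHOS_ADP", "CYTC_TEST", "OLIGOMYCIN",
                  "ETS_FCCP", "ROTENONE", "ANTIMYCIN")

.regime_names <- c("PYR_PRO", "G3P", "PC_MAL")
.preparations <- c("ISOLATED_MITO", "PERMEABILIZED_MUSCLE")

#' Substrate regime of a SUIT run
#'
#' A substrate regime names the oxidizable substrate combination loaded at the
#' start of a titration run and carries the final reagent concentrations.
#' Three regimes are supported: `PYR_PRO` (pyruvate + proline, complex-I
#' linked), `G3P` (sn-glycerol-3-phosphate, oxidized by mitochondrial G3P
#' dehydrogenase; always run after rotenone pretreatment so that electrons
#' cannot back-flow into complex I), and `PC_MAL` (palmitoylcarnitine +
#' malate, beta-oxidation via ETF:QOR).
#'
#' @param name one of `"PYR_PRO"`, `"G3P"`, `"PC_MAL"`.
#' @param concentrations optional named list overriding the default final
#'   concentrations (character strings with units, e.g. `"10 mM"`).
#' @return an object of class `suit_regime` with fields `name`,
#'   `concentrations` and `rotenone_pretreated`.
#' @examples
#' suit_regime("G3P")$rotenone_pretreated
#' @export
suit_regime <- function(name, concentrations = NULL) {
  name <- match.arg(name, .regime_names)
  defaults <- switch(name,
    PYR_PRO = list(pyruvate = "10 mM", proline = "10 mM"),
    G3P     = list(`sn-glycerol-3-phosphate` = "20 mM", rotenone = "0.5 uM"),
    PC_MAL  = list(palmitoylcarnitine = "10 uM", malate = "10 mM"))
  if (!is.null(concentrations)) {
    stopifnot(is.list(concentrations), !is.null(names(concentrations)))
    defaults[names(concentrations)] <- concentrations
  }
  structure(list(name = name,
                 concentrations = defaults,
                 rotenone_pretreated = identical(name, "G3P")),
            class = "suit_regime")
}

as_suit_regime <- function(x) {
  if (inherits(x, "suit_regime")) return(x)
  if (is.character(x) && length(x) == 1L) return(suit_regime(x))
  stop("`regime` must be a suit_regime object or a regime name ",
       "(one of ", paste(.regime_names, collapse = ", "), ")")
}

#' Run metadata for a respirometry or fluorimetry run
#'
#' @param preparation `"ISOLATED_MITO"` or `"PERMEABILIZED_MUSCLE"`.
#' @param sex `"FEMALE"` or `"MALE"`.
#' @param protein_mg mitochondrial protein in the chamber (mg); required for
#'   isolated mitochondria. Default 0.2 mg.
#' @param thorax_count number of thoraxes in the chamber; required for
#'   permeabilized muscle. Default 1.
#' @param chamber_volume_mL chamber volume in mL (default 2.2).
#' @param temperature_C assay temperature (default 27.5).
#' @return an object of class `run_meta`.
#' @examples
#' run_meta("ISOLATED_MITO", "FEMALE")
#' @export
run_meta <- function(preparation, sex = c("FEMALE", "MALE"),
                     protein_mg = NULL, thorax_count = NULL,
                     chamber_volume_mL = 2.2, temperature_C = 27.5) {
  preparation <- match.arg(preparation, .preparations)
  sex <- match.arg(sex)
  if (preparation == "ISOLATED_MITO") {
    if (is.null(protein_mg)) protein_mg <- 0.2
    if (!is.numeric(protein_mg) || protein_mg <= 0)
      stop("protein_mg must be > 0 for an ISOLATED_MITO preparation")
  } else {
    if (is.null(thorax_count)) thorax_count <- 1L
    if (thorax_count < 1) stop("thorax_count must be >= 1 for PERMEABILIZED_MUSCLE")
  }
  stopifnot(chamber_volume_mL > 0)
  structure(list(preparation = preparation, sex = sex,
                 protein_mg = protein_mg, thorax_count = thorax_count,
                 chamber_volume_mL = chamber_volume_mL,
                 temperature_C = temperature_C),
            class = "run_meta")
}

#' @export
print.run_meta <- function(x, ...) {
  cat("Run metadata:", x$preparation, "/", x$sex, "\n")
  if (x$preparation == "ISOLATED_MITO")
    cat("  protein:", x$protein_mg, "mg\n")
  else
    cat("  thoraxes:", x$thorax_count, "\n")
  cat("  chamber:", x$chamber_volume_mL, "mL at", x$temperature_C, "C\n")
  invisible(x)
}

#' Build the canonical SUIT titration protocol for a regime
#'
#' Returns the ordered template of titration events defining the metabolic
#' states of a run. The respirometry sequence is substrates (LEAK) -> ADP
#' (OXPHOS, read after the final 2 mM shot) -> cytochrome c (integrity test
#' only) -> FCCP (maximal uncoupled respiration) -> rotenone -> antimycin A.
#' The fluorimetric ROS sequence replaces the cytochrome-c test with
#' oligomycin before FCCP. G3P runs are rotenone-pretreated, so they carry no
#' distinct ROTENONE state in either sequence.
#'
#' @param regime a [suit_regime()] or regime name.
#' @param preparation `"ISOLATED_MITO"` or `"PERMEABILIZED_MUSCLE"`.
#' @param assay `"respirometry"` (oxygraph) or `"ros"` (Amplex red
#'   fluorimetry).
#' @param state_duration_s nominal spacing between titration events in the
#'   template (seconds, default 240).
#' @return an object of class `suit_protocol`: a list with the regime,
#'   preparation, assay, the ordered `events` data frame
#'   (`time_s`, `reagent`, `final_concentration`, `state`) and the state
#'   order.
#' @examples
#' p <- suit_protocol("PYR_PRO", "ISOLATED_MITO")
#' p$states
#' @export
suit_protocol <- function(regime, preparation = "ISOLATED_MITO",
                          assay = c("respirometry", "ros"),
                          state_duration_s = 240) {
  regime <- as_suit_regime(regime)
  preparation <- match.arg(preparation, .preparations)
  assay <- match.arg(assay)
  stopifnot(state_duration_s > 0)

  subst <- paste(names(regime$concentrations), collapse = " + ")
  subst_conc <- paste(unlist(regime$concentrations), collapse = " + ")
  fccp_conc <- if (assay == "ros") "2 uM"
               else if (preparation == "PERMEABILIZED_MUSCLE") "2.5 uM" else "2 uM"

  rows <- list(c(subst, subst_conc, "LEAK"),
               c("ADP", "2 mM", "OXPHOS_ADP"))
  if (assay == "respirometry")
    rows <- c(rows, list(c("cytochrome c", "10 uM", "CYTC_TEST")))
  else
    rows <- c(rows, list(c("oligomycin", "4 ug/mL", "OLIGOMYCIN")))
  rows <- c(rows, list(c("FCCP", fccp_conc, "ETS_FCCP")))
  if (!regime$rotenone_pretreated)
    rows <- c(rows, list(c("rotenone", "0.5 uM", "ROTENONE")))
  rows <- c(rows, list(c("antimycin A", "2.5 ug/mL", "ANTIMYCIN")))

  events <- data.frame(
    time_s = state_duration_s * (seq_along(rows) - 1L),
    reagent = vapply(rows, `[`, "", 1L),
    final_concentration = vapply(rows, `[`, "", 2L),
    state = vapply(rows, `[`, "", 3L),
    stringsAsFactors = FALSE)

  structure(list(regime = regime, preparation = preparation, assay = assay,
                 state_duration_s = state_duration_s,
                 events = events, states = events$state),
            class = "suit_protocol")
}

#' @export
print.suit_protocol <- function(x, ...) {
  cat(sprintf("SUIT %s protocol: %s, %s\n", x$assay, x$regime$name,
              x$preparation))
  if (x$regime$rotenone_pretreated)
    cat("  (rotenone present from the start; no distinct ROTENONE state)\n")
  print(x$events, row.names = FALSE)
  invisible(x)
}

#' Serialize / restore a SUIT protocol
#'
#' Protocols round-trip through a human-editable YAML document so that
#' non-default titration sequences can be version-controlled next to the
#' data they describe.
#'
#' @param protocol a [suit_protocol()].
#' @param path file to write; if `NULL` the YAML text is returned.
#' @return `write_protocol()` returns the YAML string invisibly (or writes
#'   the file); `read_protocol()` returns the restored `suit_protocol`.
#' @examples
#' p <- suit_protocol("G3P", "ISOLATED_MITO")
#' q <- read_protocol(text = write_protocol(p))
#' identical(p$events, q$events)
#' @export
write_protocol <- function(protocol, path = NULL) {
  stopifnot(inherits(protocol, "suit_protocol"))
  doc <- list(
    regime = list(name = protocol$regime$name,
                  concentrations = protocol$regime$concentrations,
                  rotenone_pretreated = protocol$regime$rotenone_pretreated),
    preparation = protocol$preparation,
    assay = protocol$assay,
    state_duration_s = protocol$state_duration_s,
    events = lapply(seq_len(nrow(protocol$events)), function(i)
      as.list(protocol$events[i, , drop = FALSE])))
  txt <- yaml::as.yaml(doc)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' @param text YAML text (alternative to `path`).
#' @rdname write_protocol
#' @export
read_protocol <- function(path = NULL, text = NULL) {
  doc <- if (!is.null(text)) yaml::yaml.load(text) else yaml::read_yaml(path)
  regime <- suit_regime(doc$regime$name, doc$regime$concentrations)
  ev <- do.call(rbind, lapply(doc$events, function(e)
    data.frame(time_s = as.numeric(e$time_s), reagent = e$reagent,
               final_concentration = e$final_concentration, state = e$state,
               stringsAsFactors = FALSE)))
  out <- suit_protocol(regime, doc$preparation, doc$assay,
                       doc$state_duration_s)
  ## honour hand-edited event tables (times, reagents) verbatim
  out$events <- ev
  out$states <- ev$state
  out
}

## states whose rates feed the site decomposition, per regime
required_states <- function(regime, assay = c("respirometry", "ros")) {
  regime <- as_suit_regime(regime)
  assay <- match.arg(assay)
  if (regime$rotenone_pretreated) c("ETS_FCCP", "ANTIMYCIN")
  else c("ETS_FCCP", "ROTENONE", "ANTIMYCIN")
}
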