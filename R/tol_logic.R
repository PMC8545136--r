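GENOTYPES <- c("WT_pWW0", "PAW140_CHROMOSOMAL", "PUXT7_IN_MT2", "PUXT7_IN_T7_HOST")
INDUCERS  <- c("NONE", "M_XYLENE", "TOLUENE", "O_XYLENE", "BENZOATE", "MBZ3")
LEVELS    <- c("OFF", "LOW", "HIGH")

#' Define an experimental condition for the TOL system
#'
#' A condition bundles the host/plasmid genotype, the aromatic inducer, and
#' the two treatments (IPTG, rifampin) that together determine which *xyl*
#' transcripts a cell expresses.
#'
#' Genotypes:
#' \describe{
#'   \item{WT_pWW0}{Wild-type host carrying the native TOL plasmid pWW0.}
#'   \item{PAW140_CHROMOSOMAL}{Both *xyl* operons and their regulators
#'     integrated in the chromosome; induction logic identical to WT_pWW0 but
#'     with a higher per-cell focus count (see [sim_params()]).}
#'   \item{PUXT7_IN_MT2}{pWW0 variant whose *Pu* promoter is replaced by a T7
#'     promoter, hosted in a strain without T7 RNA polymerase: the upper
#'     operon is never transcribed.}
#'   \item{PUXT7_IN_T7_HOST}{The same plasmid in a host expressing T7 RNA
#'     polymerase from a chromosomal lacIq/Plac cassette; IPTG induces the
#'     upper operon and the cassette is slightly leaky without IPTG.}
#' }
#'
#' @param genotype one of `"WT_pWW0"`, `"PAW140_CHROMOSOMAL"`,
#'   `"PUXT7_IN_MT2"`, `"PUXT7_IN_T7_HOST"`.
#' @param inducer one of `"NONE"`, `"M_XYLENE"`, `"TOLUENE"`, `"O_XYLENE"`,
#'   `"BENZOATE"`, `"MBZ3"` (3-methyl benzoate).
#' @param iptg logical; only meaningful for `PUXT7_IN_T7_HOST`, ignored (but
#'   retained) otherwise.
#' @param rifampin logical; inhibits the host RNA polymerase but not T7 RNA
#'   polymerase, and disperses any remaining signal.
#' @return an object of class `tol_condition`.
#' @examples
#' tol_condition("WT_pWW0", "M_XYLENE")
#' @export
tol_condition <- function(genotype = "WT_pWW0", inducer = "NONE",
                          iptg = FALSE, rifampin = FALSE) {
  genotype <- match.arg(genotype, GENOTYPES)
  inducer <- match.arg(inducer, INDUCERS)
  stopifnot(is.logical(iptg), length(iptg) == 1L, !is.na(iptg),
            is.logical(rifampin), length(rifampin) == 1L, !is.na(rifampin))
  structure(list(genotype = genotype, inducer = inducer,
                 iptg = iptg, rifampin = rifampin),
            class = "tol_condition")
}

#' @export
print.tol_condition <- function(x, ...) {
  cat(sprintf("<tol_condition> %s + %s%s%s\n", x$genotype, x$inducer,
              if (x$iptg) " +IPTG" else "",
              if (x$rifampin) " +rifampin" else ""))
  invisible(x)
}

#' Which transcripts does a condition express?
#'
#' Discrete (three-level) model of the TOL regulatory cascade. Upper-pathway
#' effectors (m-xylene, toluene, o-xylene) activate XylR, which fires the *Pu*
#' promoter driving *xylUW* and overproduces XylS, which in turn fires *Pm*
#' driving *xylX*; lower-pathway substrates (benzoate, 3-methyl benzoate)
#' activate XylS directly, giving *xylX* only. When *Pu* is replaced by a T7
#' promoter, *xylUW* depends on T7 RNA polymerase (IPTG-induced; leaky LOW
#' without IPTG), and full T7 activation drives *xylX* as well. Rifampin
#' silences every host-polymerase transcript but not T7-driven *xylUW*, and
#' renders remaining signal dispersed rather than focal.
#'
#' @param cond a [tol_condition()].
#' @return an object of class `expression_state`: list with `levels` (named
#'   character vector over `xylUW`, `xylX` with values `"OFF"`, `"LOW"`,
#'   `"HIGH"`) and `focal` (logical; `FALSE` only under rifampin).
#' @examples
#' expressed_transcripts(tol_condition("WT_pWW0", "BENZOATE"))
#' @export
expressed_transcripts <- function(cond) {
  stopifnot(inherits(cond, "tol_condition"))
  upper_eff <- cond$inducer %in% c("M_XYLENE", "TOLUENE", "O_XYLENE")
  lower_eff <- cond$inducer %in% c("BENZOATE", "MBZ3")

  xylUW <- "OFF"
  xylX <- "OFF"
  if (cond$genotype %in% c("WT_pWW0", "PAW140_CHROMOSOMAL")) {
    if (upper_eff) xylUW <- "HIGH"
    if (upper_eff || lower_eff) xylX <- "HIGH"
  } else if (cond$genotype == "PUXT7_IN_MT2") {
    # Pu replaced by PT7, no T7 polymerase in the host: upper operon silent.
    # XylR/XylS cascade on the plasmid is intact, so Pm still fires.
    if (upper_eff || lower_eff) xylX <- "HIGH"
  } else { # PUXT7_IN_T7_HOST
    xylUW <- if (cond$iptg) "HIGH" else "LOW" # leaky Plac-T7pol cassette
    if (cond$iptg || upper_eff || lower_eff) xylX <- "HIGH"
  }

  if (cond$rifampin) {
    # Host RNAP is blocked; T7 RNAP is insensitive, so only the T7-driven
    # upper transcript survives. Pm is always host-transcribed.
    xylX <- "OFF"
    if (cond$genotype != "PUXT7_IN_T7_HOST") xylUW <- "OFF"
  }

  structure(list(levels = c(xylUW = xylUW, xylX = xylX),
                 focal = !cond$rifampin),
            class = "expression_state")
}

#' @export
print.expression_state <- function(x, ...) {
  cat(sprintf("<expression_state> xylUW=%s xylX=%s focal=%s\n",
              x$levels[["xylUW"]], x$levels[["xylX"]], x$focal))
  invisible(x)
}

#' Enumerate all conditions of the truth table
#'
#' Expands every genotype x inducer x IPTG x rifampin combination (96 rows)
#' together with the expression state the model assigns to each. Useful for
#' auditing totality and monotonicity of the regulatory logic.
#'
#' @return data.frame with one row per condition and columns `genotype`,
#'   `inducer`, `iptg`, `rifampin`, `xylUW`, `xylX`, `focal`.
#' @export
expression_truth_table <- function() {
  grid <- expand.grid(genotype = GENOTYPES, inducer = INDUCERS,
                      iptg = c(FALSE, TRUE), rifampin = c(FALSE, TRUE),
                      stringsAsFactors = FALSE)
  states <- lapply(seq_len(nrow(grid)), function(i) {
    expressed_transcripts(tol_condition(grid$genotype[i], grid$inducer[i],
                                        grid$iptg[i], grid$rifampin[i]))
  })
  grid$xylUW <- vapply(states, function(s) s$levels[["xylUW"]], character(1))
  grid$xylX <- vapply(states, function(s) s$levels[["xylX"]], character(1))
  grid$focal <- vapply(states, function(s) s$focal, logical(1))
  grid
}
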