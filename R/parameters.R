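#' Binding constant for a pair of interaction partners
#'
#' A `binding_constant` records the equilibrium dissociation constant of one
#' pairwise interaction in the Cyp33/MLL1/H3K4me3/RNA system. Partner labels
#' follow the species naming used throughout the package: `M` (the MLL1
#' PHD3-BRD reader module), `H` (the H3K4me3 histone tail peptide), `C`
#' (Cyp33), `R` (one RNA binding site), and complexes named by concatenation
#' (`CM` = Cyp33 bound to the MLL1 reader). Protein variants are suffixed with
#' an underscore, e.g. `C_WLF` for the Cyp33 W101A/L102A/F105A helix mutant.
#'
#' @param pair character vector of length 2, the two partner labels. Order is
#'   preserved and the pair id is `"A:B"`.
#' @param kd dissociation constant in micromolar. Must be positive and finite.
#' @param censored logical; `TRUE` when `kd` is only a lower bound (binding too
#'   weak to quantify). Censored constants are refused by kinetic conversions
#'   and by network construction.
#' @param source free-text provenance tag (assay and construct).
#' @param derived logical; `TRUE` when the value was produced by thermodynamic
#'   cycle closure rather than measured. Derived constants cannot be
#'   overridden or scanned.
#' @return An object of class `binding_constant`.
#' @seealso [parameter_set()], [rates_for()], [close_cycle()]
#' @export
binding_constant <- function(pair, kd, censored = FALSE, source = "",
                             derived = FALSE) {
  stopifnot(is.character(pair), length(pair) == 2L, nzchar(pair))
  if (!is.numeric(kd) || length(kd) != 1L || !is.finite(kd) || kd <= 0)
    stop("'kd' must be a single positive finite value (uM)", call. = FALSE)
  structure(
    list(pair = pair, pair_id = paste(pair, collapse = ":"),
         kd = as.numeric(kd), censored = isTRUE(censored),
         source = as.character(source), derived = isTRUE(derived)),
    class = "binding_constant")
}

#' @export
print.binding_constant <- function(x, ...) {
  cat(sprintf("<binding_constant> %s: Kd %s %g uM%s%s\n", x$pair_id,
              if (x$censored) ">" else "=", x$kd,
              if (x$derived) " [derived]" else "",
              if (nzchar(x$source)) paste0("  (", x$source, ")") else ""))
  invisible(x)
}

#' Collection of binding constants with a default association rate
#'
#' A `parameter_set` holds measured [binding_constant()] entries keyed by pair
#' id, plus any constants derived by detailed-balance cycle closure and the
#' default association rate constant used to convert dissociation constants
#' into kinetic rate pairs. Units are micromolar, seconds and uM^-1 s^-1
#' throughout.
#'
#' @param constants list of [binding_constant()] objects; pair ids must be
#'   unique.
#' @param kon_default default bimolecular association rate constant,
#'   uM^-1 s^-1. The packaged default of 10 (1e7 M^-1 s^-1) is a standard
#'   diffusion-limited estimate for protein association.
#' @param derive logical; derive detailed-balance cycle closures (currently the
#'   `C:MH` edge from `C:M`, `CM:H` and `M:H`) when the parent constants are
#'   present.
#' @return An object of class `parameter_set` with elements `constants`
#'   (named list of measured constants), `derived` (named list of derived
#'   constants) and `kon_default`.
#' @export
parameter_set <- function(constants, kon_default = 10, derive = TRUE) {
  stopifnot(is.list(constants),
            all(vapply(constants, inherits, logical(1), "binding_constant")))
  ids <- vapply(constants, `[[`, character(1), "pair_id")
  if (anyDuplicated(ids))
    stop("duplicate pair ids: ", paste(unique(ids[duplicated(ids)]),
                                       collapse = ", "), call. = FALSE)
  if (!is.numeric(kon_default) || length(kon_default) != 1L || kon_default <= 0)
    stop("'kon_default' must be a single positive value (uM^-1 s^-1)",
         call. = FALSE)
  names(constants) <- ids
  ps <- structure(list(constants = constants, derived = list(),
                       kon_default = as.numeric(kon_default)),
                  class = "parameter_set")
  if (derive) ps <- derive_cycle_constants(ps)
  ps
}

#' @export
print.parameter_set <- function(x, ...) {
  cat(sprintf("<parameter_set> %d measured + %d derived constants, kon_default %g uM^-1 s^-1\n",
              length(x$constants), length(x$derived), x$kon_default))
  for (bc in x$constants) print(bc)
  for (bc in x$derived) print(bc)
  invisible(x)
}

#' Look up a binding constant by pair id
#'
#' @param ps a [parameter_set()].
#' @param pair_id pair id string such as `"C:M"`. Measured and derived
#'   constants are both searched.
#' @param required error (rather than return `NULL`) when absent.
#' @return A [binding_constant()] or `NULL`.
#' @export
get_constant <- function(ps, pair_id, required = TRUE) {
  stopifnot(inherits(ps, "parameter_set"))
  bc <- ps$constants[[pair_id]]
  if (is.null(bc)) bc <- ps$derived[[pair_id]]
  if (is.null(bc) && required)
    stop("missing constant ", pair_id, call. = FALSE)
  bc
}

#' Thermodynamic cycle closure for the ternary complex
#'
#' Around the four-state cycle M, M+H -> MH, M+C -> CM, CM+H -> CMH the product
#' of equilibrium constants must equal one (detailed balance). Given the
#' dissociation constants for C binding free M (`kd_CM`), H binding the CM
#' complex (`kd_H_given_CM`), and H binding free M (`kd_H_given_M`), the
#' dissociation constant for C binding the preformed MH complex is fixed:
#'
#' \deqn{K_{C|MH} = K_{CM} \, K_{H|CM} / K_{H|M}}
#'
#' With the packaged defaults (4.6, 70 and 4 uM) this yields 80.5 uM: because
#' Cyp33 weakens the reader's grip on the histone mark, the histone mark
#' reciprocally weakens Cyp33 binding by the same thermodynamic factor.
#'
#' @param kd_CM,kd_H_given_CM,kd_H_given_M dissociation constants, uM; all
#'   positive.
#' @return The dissociation constant of C from the full ternary complex when
#'   binding to preformed MH, in uM.
#' @export
close_cycle <- function(kd_CM, kd_H_given_CM, kd_H_given_M) {
  vals <- c(kd_CM, kd_H_given_CM, kd_H_given_M)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("cycle closure requires positive finite dissociation constants",
         call. = FALSE)
  kd_CM * kd_H_given_CM / kd_H_given_M
}

# Attach detailed-balance-derived constants. The C:MH edge is always derived,
# never settable, so the M/MH/CM/CMH cycle cannot become inconsistent.
derive_cycle_constants <- function(ps) {
  cm <- ps$constants[["C:M"]]
  cmh <- ps$constants[["CM:H"]]
  mh <- ps$constants[["M:H"]]
  ps$derived <- list()
  if (!is.null(cm) && !is.null(cmh) && !is.null(mh)) {
    if (!is.null(ps$constants[["C:MH"]]))
      stop("'C:MH' is derived by cycle closure and cannot be set directly",
           call. = FALSE)
    kd <- close_cycle(cm$kd, cmh$kd, mh$kd)
    ps$derived[["C:MH"]] <- binding_constant(
      c("C", "MH"), kd, source = "detailed balance: C:M x CM:H / M:H",
      derived = TRUE)
    # invariant: product of equilibrium constants around the cycle is 1
    resid <- abs(cm$kd * cmh$kd / (mh$kd * kd) - 1)
    if (resid > 1e-9)
      stop("cycle closure residual ", format(resid), " exceeds 1e-9")
  }
  ps
}

#' Packaged dissociation constants of the Cyp33/MLL1/H3K4me3/RNA system
#'
#' Returns the curated set of measured equilibrium dissociation constants for
#' the switch: the MLL1 PHD3-BRD reader on H3K4me3, Cyp33 RRM on the MLL1
#' PHD3, the histone mark on the Cyp33-bound reader (with and without the
#' regulatory alpha3 helix), Cyp33 wild type and RNA-binding-surface mutants
#' on the UAAUGU RNA motif, and the RNA-H3K4me3 tail interaction. The triple
#' lysine/arginine mutant's RNA affinity is below detection and is stored as a
#' censored lower bound. The `C:MH` ternary-assembly edge is derived by
#' detailed balance (80.5 uM from the defaults).
#'
#' Only the wild-type entries participate in the default reaction network;
#' mutant and isolated-domain entries are carried for assay-recovery work.
#'
#' @return A [parameter_set()] with `kon_default` 10 uM^-1 s^-1.
#' @export
default_parameter_set <- function() {
  parameter_set(list(
    binding_constant(c("M", "H"), 4,
                     source = "ITC, MLL1 PHD3-BRD reader + H3K4me3 peptide"),
    binding_constant(c("PHD3", "H"), 51,
                     source = "ITC, isolated MLL1 PHD3 + H3K4me3 peptide"),
    binding_constant(c("C", "M"), 4.6,
                     source = "ITC, Cyp33 RRM + MLL1 PHD3"),
    binding_constant(c("CM", "H"), 70,
                     source = "ITC, Cyp33 RRM:PHD3 complex + H3K4me3"),
    binding_constant(c("CMda", "H"), 24,
                     source = "ITC, Cyp33 RRM(delta-alpha3):PHD3 complex + H3K4me3"),
    binding_constant(c("C", "R"), 300,
                     source = "NMR titration, Cyp33 WT + UAAUGU RNA"),
    binding_constant(c("C_WLF", "R"), 70,
                     source = "NMR titration + ITC, Cyp33 W101A/L102A/F105A + UAAUGU"),
    binding_constant(c("C_K83A", "R"), 1800,
                     source = "NMR titration, Cyp33 K83A + UAAUGU"),
    binding_constant(c("C_RK", "R"), 2000,
                     source = "NMR titration, Cyp33 R86A/K88A + UAAUGU"),
    binding_constant(c("C_KRK", "R"), 10000, censored = TRUE,
                     source = "NMR titration, Cyp33 K83A/R86A/K88A + UAAUGU; lower bound"),
    binding_constant(c("R", "H"), 30,
                     source = "ITC, repeat RNA + H3K4me3 peptide")),
    kon_default = 10)
}

#' Convert a dissociation constant into a kinetic rate pair
#'
#' Under the diffusion-limit approximation every association proceeds at the
#' same `kon`, and the dissociation rate follows from the equilibrium
#' requirement `koff = kon * kd`.
#'
#' @param constant a [binding_constant()]; must not be censored.
#' @param kon_default association rate constant, uM^-1 s^-1.
#' @return A list with elements `kon` (uM^-1 s^-1) and `koff` (s^-1).
#' @export
rates_for <- function(constant, kon_default = 10) {
  stopifnot(inherits(constant, "binding_constant"))
  if (constant$censored)
    stop("constant ", constant$pair_id, " is censored (Kd > ", constant$kd,
         " uM, lower bound only) and cannot be used kinetically", call. = FALSE)
  if (!is.numeric(kon_default) || length(kon_default) != 1L || kon_default <= 0)
    stop("'kon_default' must be a single positive value", call. = FALSE)
  list(kon = kon_default, koff = kon_default * constant$kd)
}

#' Replace one measured dissociation constant
#'
#' Returns a modified [parameter_set()] with the given pair's `kd` replaced
#' and all derived cycle-closure constants recomputed. The derived `C:MH`
#' edge cannot be targeted: it is fixed by detailed balance.
#'
#' @param ps a [parameter_set()].
#' @param pair_id pair id of a measured (non-derived) constant.
#' @param kd new dissociation constant, uM.
#' @return A [parameter_set()].
#' @export
set_constant <- function(ps, pair_id, kd) {
  stopifnot(inherits(ps, "parameter_set"))
  if (!is.null(ps$derived[[pair_id]]))
    stop("constant ", pair_id,
         " is derived by detailed balance and cannot be set or scanned",
         call. = FALSE)
  bc <- ps$constants[[pair_id]]
  if (is.null(bc)) stop("missing constant ", pair_id, call. = FALSE)
  ps$constants[[pair_id]] <- binding_constant(bc$pair, kd,
                                              censored = bc$censored,
                                              source = bc$source)
  derive_cycle_constants(ps)
}

#' Read and write parameter files
#'
#' Parameter files are YAML mappings with top-level keys `species` (monomer
#' labels), `kon_default` (uM^-1 s^-1) and `constants`, a list of entries
#' `{pair: [A, B], kd_uM: x, censored: bool, source: text}`. Derived constants
#' are recomputed on read, never stored. A packaged default file ships at
#' `system.file("extdata", "binding_constants.yaml", package = "cyp33switch")`.
#'
#' @param path file path.
#' @param ps a [parameter_set()].
#' @return `read_parameter_set()` returns a [parameter_set()];
#'   `write_parameter_set()` returns `path` invisibly.
#' @export
read_parameter_set <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$constants))
    stop("parameter file ", path, " has no 'constants' key", call. = FALSE)
  constants <- lapply(doc$constants, function(e) {
    binding_constant(as.character(unlist(e$pair)), e$kd_uM,
                     censored = isTRUE(e$censored),
                     source = if (is.null(e$source)) "" else e$source)
  })
  kon <- if (is.null(doc$kon_default)) 10 else doc$kon_default
  parameter_set(constants, kon_default = kon)
}

#' @rdname read_parameter_set
#' @export
write_parameter_set <- function(ps, path) {
  stopifnot(inherits(ps, "parameter_set"))
  species <- sort(unique(unlist(lapply(ps$constants, `[[`, "pair"))))
  doc <- list(
    species = as.list(species),
    kon_default = ps$kon_default,
    constants = lapply(unname(ps$constants), function(bc) {
      list(pair = as.list(bc$pair), kd_uM = bc$kd,
           censored = bc$censored, source = bc$source)
    }))
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}
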