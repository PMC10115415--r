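# Reaction network of the chromatin switch.
#
# Species labels: M (MLL1 PHD3-BRD reader), H (H3K4me3 tail), C (Cyp33),
# R (one RNA site), and the complexes MH, CM, CMH, CR, RH named by
# concatenation of their monomer composition. RNA and MLL1 compete for the
# same surface of Cyp33, and Cyp33 or H3K4me3 occupy the single RNA site
# exclusively, so no CR-containing ternary exists.

default_reaction_table <- function() {
  list(
    list(pair_id = "M:H",  reactants = c("M", "H"),  product = "MH"),
    list(pair_id = "C:M",  reactants = c("C", "M"),  product = "CM"),
    list(pair_id = "CM:H", reactants = c("CM", "H"), product = "CMH"),
    list(pair_id = "C:R",  reactants = c("C", "R"),  product = "CR"),
    list(pair_id = "R:H",  reactants = c("R", "H"),  product = "RH"),
    list(pair_id = "C:MH", reactants = c("C", "MH"), product = "CMH"))
}

default_composition <- function() {
  list(M = c(M = 1), H = c(H = 1), C = c(C = 1), R = c(R = 1),
       MH = c(M = 1, H = 1), CM = c(C = 1, M = 1),
       CMH = c(C = 1, M = 1, H = 1), CR = c(C = 1, R = 1),
       RH = c(R = 1, H = 1))
}

#' Build the mass-action reaction network of the switch
#'
#' Assembles the default reversible network from a [parameter_set()]:
#' `M+H <-> MH`, `C+M <-> CM`, `CM+H <-> CMH`, `C+R <-> CR`, `R+H <-> RH`,
#' plus the detailed-balance-derived assembly route `C+MH <-> CMH`. All on
#' rates equal `kon_default`; off rates follow from the dissociation
#' constants via [rates_for()]. Species are ordered lexicographically so
#' stoichiometry matrices are reproducible.
#'
#' @param params a [parameter_set()] containing (at least) the pairs
#'   `M:H`, `C:M`, `CM:H`, `C:R` and `R:H`. A missing pair is an error naming
#'   it; a censored pair is refused.
#' @return An object of class `reaction_network` with elements `species`,
#'   `monomers`, `composition`, `reactions` (each with `reactants`, `product`,
#'   `kon`, `koff`, `kd`, `pair_id`), the stoichiometry matrix `stoich`
#'   (species x reactions) and `conservation` (per-monomer multiplicity
#'   vectors over species).
#' @examples
#' net <- build_network(default_parameter_set())
#' length(net$reactions)  # 6 reversible reactions
#' @export
build_network <- function(params) {
  stopifnot(inherits(params, "parameter_set"))
  tab <- default_reaction_table()
  composition <- default_composition()
  species <- sort(names(composition))
  monomers <- sort(names(which(vapply(composition, sum, numeric(1)) == 1)))

  reactions <- lapply(tab, function(rx) {
    bc <- get_constant(params, rx$pair_id)
    rates <- rates_for(bc, params$kon_default)
    list(pair_id = rx$pair_id, reactants = rx$reactants, product = rx$product,
         kd = bc$kd, kon = rates$kon, koff = rates$koff)
  })

  stoich <- matrix(0, nrow = length(species), ncol = length(reactions),
                   dimnames = list(species, vapply(reactions, `[[`,
                                                   character(1), "pair_id")))
  for (j in seq_along(reactions)) {
    rx <- reactions[[j]]
    for (sp in rx$reactants) stoich[sp, j] <- stoich[sp, j] - 1
    stoich[rx$product, j] <- stoich[rx$product, j] + 1
  }

  conservation <- lapply(monomers, function(m) {
    vapply(species, function(sp) {
      cmp <- composition[[sp]]
      if (m %in% names(cmp)) unname(cmp[m]) else 0
    }, numeric(1))
  })
  names(conservation) <- monomers

  # every conservation vector must be in the left null space of the
  # stoichiometry matrix (monomer composition balanced per reaction)
  for (m in monomers) {
    if (max(abs(conservation[[m]] %*% stoich)) > 0)
      stop("reaction list does not conserve monomer ", m)
  }

  structure(list(species = species, monomers = monomers,
                 composition = composition, reactions = reactions,
                 stoich = stoich, conservation = conservation),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network> %d species, %d reversible reactions\n",
              length(x$species), length(x$reactions)))
  for (rx in x$reactions)
    cat(sprintf("  %s + %s <-> %s   Kd %g uM (kon %g, koff %g)\n",
                rx$reactants[1], rx$reactants[2], rx$product,
                rx$kd, rx$kon, rx$koff))
  invisible(x)
}

# reaction rates: v_j = kon * prod(reactants) - koff * product
reaction_rates <- function(network, conc) {
  conc <- pmax(conc, 0)
  vapply(network$reactions, function(rx) {
    rx$kon * prod(conc[rx$reactants]) - rx$koff * conc[rx$product]
  }, numeric(1))
}

# internal rhs without validation, shared by the integrator
rhs_raw <- function(network, conc, synthesis = NULL, decay = NULL) {
  dx <- as.numeric(network$stoich %*% reaction_rates(network, conc))
  names(dx) <- network$species
  if (!is.null(synthesis))
    dx[names(synthesis)] <- dx[names(synthesis)] + synthesis
  if (!is.null(decay))   # first-order removal of the free monomer only
    dx[names(decay)] <- dx[names(decay)] - decay * pmax(conc[names(decay)], 0)
  dx
}

#' Mass-action time derivatives
#'
#' Evaluates the ODE right-hand side of a [build_network()] model: each
#' reversible reaction contributes `kon * [A][B]` towards its complex and
#' `koff * [AB]` back. The derivative vector is orthogonal to every
#' conservation vector by construction.
#'
#' @param network a `reaction_network`.
#' @param state named concentration vector over `network$species`, uM.
#' @param tol concentrations below `-tol` are an error; small negative
#'   excursions within the tolerance are treated as zero.
#' @return Named vector of time derivatives, uM/s.
#' @export
ode_rhs <- function(network, state, tol = 1e-9) {
  stopifnot(inherits(network, "reaction_network"))
  state <- state[network$species]
  if (anyNA(state))
    stop("state must name every network species", call. = FALSE)
  if (any(state < -tol))
    stop("negative concentration beyond tolerance: ",
         paste(network$species[state < -tol], collapse = ", "), call. = FALSE)
  rhs_raw(network, state)
}

#' Closed-form bound fraction for one-to-one binding
#'
#' Exact solution of the single-site equilibrium `P + L <-> PL`:
#' \deqn{[PL] = \frac{(P_t + L_t + K_d) - \sqrt{(P_t + L_t + K_d)^2 - 4 P_t L_t}}{2}}
#' returned as the fraction of `P` in complex. This is the oracle for every
#' two-species subnetwork and the forward model inside the titration and ITC
#' fitters.
#'
#' @param p_total,l_total total concentrations of the observed species and its
#'   ligand, uM; non-negative. Vectorised over `l_total`.
#' @param kd dissociation constant, uM; positive.
#' @return Bound fraction in `[0, 1]`; 0 where `p_total` is 0.
#' @export
bound_fraction_1to1 <- function(p_total, l_total, kd) {
  stopifnot(all(p_total >= 0), all(l_total >= 0), kd > 0)
  s <- p_total + l_total + kd
  disc <- pmax(s^2 - 4 * p_total * l_total, 0)
  pl <- 2 * p_total * l_total / (s + sqrt(disc))  # stable form of (s - sqrt)/2
  p <- rep_len(p_total, length(pl))
  ifelse(p > 0, pl / p, 0)
}

# Overall formation (association) constants of each complex from free
# monomers, Kf in uM^-(n-1), obtained by chaining reaction equilibria.
# Detailed balance guarantees path independence (validated at derivation).
formation_constants <- function(network) {
  kf <- stats::setNames(rep(NA_real_, length(network$species)),
                        network$species)
  kf[network$monomers] <- 1
  pending <- TRUE
  while (pending) {
    pending <- FALSE
    progressed <- FALSE
    for (rx in network$reactions) {
      if (is.na(kf[rx$product]) && !anyNA(kf[rx$reactants])) {
        kf[rx$product] <- prod(kf[rx$reactants]) / rx$kd
        progressed <- TRUE
      }
      if (anyNA(kf)) pending <- TRUE
    }
    if (pending && !progressed)
      stop("species unreachable from monomers: ",
           paste(names(kf)[is.na(kf)], collapse = ", "))
  }
  kf
}

#' Algebraic equilibrium of the network
#'
#' Solves the coupled competitive-binding equilibrium for given total monomer
#' concentrations by damped fixed-point iteration on the free monomer
#' concentrations (damping 0.5, cap 1e5 iterations), with a Newton fallback
#' on log free concentrations. Complex concentrations follow from the free
#' monomers through the overall formation constants, so every reaction's net
#' flux vanishes to rounding at the solution.
#'
#' @param network a `reaction_network`.
#' @param totals named non-negative totals per monomer, uM; monomers not named
#'   default to 0.
#' @param tol relative conservation tolerance required of the solution.
#' @return Named equilibrium concentration vector over all species (uM) with
#'   attributes `iterations` and `residual` (max relative conservation error).
#' @examples
#' net <- build_network(default_parameter_set())
#' eq <- equilibrate(net, c(M = 100, H = 100))
#' eq[["MH"]]  # 81.90 uM, the closed-form two-species value
#' @export
equilibrate <- function(network, totals, tol = 1e-6) {
  stopifnot(inherits(network, "reaction_network"))
  tot <- stats::setNames(rep(0, length(network$monomers)), network$monomers)
  if (!is.null(totals)) {
    unknown <- setdiff(names(totals), network$monomers)
    if (length(unknown))
      stop("unknown monomers in totals: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    if (any(totals < 0)) stop("totals must be non-negative", call. = FALSE)
    tot[names(totals)] <- totals
  }
  kf <- formation_constants(network)
  complexes <- setdiff(network$species, network$monomers)
  active <- network$monomers[tot > 0]

  conc_from_free <- function(free) {
    conc <- stats::setNames(rep(0, length(network$species)), network$species)
    conc[network$monomers] <- free
    for (sp in complexes) {
      cmp <- network$composition[[sp]]
      conc[sp] <- kf[sp] * prod(free[names(cmp)]^cmp)
    }
    conc
  }
  bound_per_free <- function(free, m) {
    # d(bound m)/d(free m) at fixed other frees; counts are all 0/1 here
    s <- 0
    for (sp in complexes) {
      cmp <- network$composition[[sp]]
      if (m %in% names(cmp))
        s <- s + cmp[[m]] * kf[sp] *
          prod(free[setdiff(names(cmp), m)]^cmp[setdiff(names(cmp), m)]) *
          free[m]^(cmp[[m]] - 1)
    }
    s
  }
  residual <- function(free) {
    conc <- conc_from_free(free)
    cons <- vapply(network$monomers,
                   function(m) sum(network$conservation[[m]] * conc),
                   numeric(1))
    max(abs(cons - tot) / pmax(tot, 1))
  }

  free <- tot  # start from the no-binding limit
  it <- 0L
  if (length(active)) {
    repeat {
      it <- it + 1L
      new <- free
      for (m in active)
        new[m] <- tot[m] / (1 + bound_per_free(free, m))
      new <- 0.5 * free + 0.5 * new
      delta <- max(abs(new - free) / pmax(tot, 1))
      free <- new
      if (delta < 1e-15 || it >= 1e5) break
    }
  }

  if (residual(free) > tol && length(active)) {
    # Newton on x = log(free) over the active monomers
    x <- log(pmax(free[active], 1e-300))
    for (k in 1:200) {
      fr <- free; fr[active] <- exp(x)
      conc <- conc_from_free(fr)
      g <- vapply(active, function(m)
        sum(network$conservation[[m]] * conc) - tot[m], numeric(1))
      if (max(abs(g) / pmax(tot[active], 1)) < 1e-13) break
      J <- matrix(0, length(active), length(active),
                  dimnames = list(active, active))
      for (sp in c(active, complexes)) {
        cmp <- network$composition[[sp]]
        inv <- intersect(names(cmp), active)
        for (mi in inv) for (mj in inv)
          J[mi, mj] <- J[mi, mj] + cmp[[mi]] * cmp[[mj]] * conc[sp]
      }
      step <- tryCatch(solve(J, g), error = function(e) g / diag(J))
      step <- pmin(pmax(step, -2), 2)
      x <- x - step
      free[active] <- exp(x)
    }
  }

  res <- residual(free)
  if (res > tol)
    stop(sprintf(
      "equilibrium solver did not converge: conservation residual %.3e after %d iterations",
      res, it), call. = FALSE)
  conc <- conc_from_free(free)
  attr(conc, "iterations") <- it
  attr(conc, "residual") <- res
  attr(conc, "time") <- 0
  conc
}

#' Integrate the network ODE, optionally with synthesis and decay
#'
#' Stiff-capable integration (deSolve `lsoda`, relative tolerance 1e-8,
#' absolute tolerance 1e-10 uM) of the mass-action model. Zeroth-order
#' synthesis feeds the named free monomers; first-order decay removes free
#' monomer only, so complexes release their partners by mass action before
#' removal.
#'
#' @param network a `reaction_network`.
#' @param state0 named initial concentrations over all species, uM.
#' @param times output time grid, s.
#' @param synthesis optional named zeroth-order rates, uM/s, per monomer.
#' @param decay optional named first-order rate constants, s^-1, per monomer.
#' @return Matrix with a `time` column and one column per species.
#' @export
integrate_network <- function(network, state0, times,
                              synthesis = NULL, decay = NULL) {
  stopifnot(inherits(network, "reaction_network"))
  y0 <- stats::setNames(rep(0, length(network$species)), network$species)
  y0[names(state0)] <- state0
  func <- function(t, y, parms) {
    names(y) <- network$species
    list(rhs_raw(network, y, synthesis, decay))
  }
  out <- deSolve::ode(y = y0, times = times, func = func, parms = NULL,
                      method = "lsoda", rtol = 1e-8, atol = 1e-10)
  if (min(out[, -1]) < -1e-9)
    stop("integration produced negative concentrations beyond tolerance at t = ",
         out[which(apply(out[, -1, drop = FALSE], 1, min) < -1e-9)[1], "time"],
         call. = FALSE)
  unclass(out)
}
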