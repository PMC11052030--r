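#' Non-bonded DPD pair parameters
#'
#' Species-pair tables of the conservative repulsion strength \code{a_ij},
#' the dissipative (friction) coefficient \code{gamma} and the cutoff radius
#' \code{r_c}.  The random-force coefficient is never stored: it is derived
#' from the fluctuation-dissipation relation \code{sigma^2 = 2 gamma kBT}
#' at force evaluation time, so the relation holds exactly by construction.
#'
#' Defaults reproduce the shipped interaction table: membrane-row pairs use
#' 100/45/0.5 (a/gamma/r_c) among the cell species, actin- and ACP-row pairs
#' use 100/65/0.25, rigid-tool pairs (probe, substrate, pipettes) use
#' 100/65/0.25 except the holding pipette (a = 30 against the membrane,
#' r_c = 0.5), and the holding/injection pipette pair does not interact at
#' all.  The solvent species (absent from the shipped table) defaults to the
#' standard soft-fluid parameterisation a = 25, gamma = 4.5, r_c = 1.
#'
#' @param kBT energy scale (reduced units); default 1.
#' @param overrides optional named list; each element is a list
#'   \code{list(i = species, j = species, a =, gamma =, rc =)} replacing one
#'   symmetric entry.
#' @return an object of class \code{pair_params}: list with matrices
#'   \code{a}, \code{gamma}, \code{rc} (rows/columns named by species) and
#'   the scalar \code{kBT}.
#' @export
pair_params <- function(kBT = 1, overrides = NULL) {
  S <- length(CYTO_SPECIES)
  a <- g <- rc <- matrix(0, S, S, dimnames = list(CYTO_SPECIES, CYTO_SPECIES))
  set <- function(i, j, trip) {
    a[i, j] <<- a[j, i] <<- trip[1]
    g[i, j] <<- g[j, i] <<- trip[2]
    rc[i, j] <<- rc[j, i] <<- trip[3]
  }
  mem <- c(100, 45, 0.5); act <- c(100, 65, 0.25)
  tool <- c(100, 65, 0.25); hold <- c(100, 65, 0.5)
  # membrane row
  set("membrane", "membrane", mem); set("membrane", "actin", mem)
  set("membrane", "acp", mem)
  set("membrane", "probe", tool); set("membrane", "substrate", tool)
  set("membrane", "holding_pipette", c(30, 65, 0.5))
  set("membrane", "injection_pipette", tool)
  # actin row
  set("actin", "actin", act); set("actin", "acp", act)
  set("actin", "probe", tool); set("actin", "substrate", tool)
  set("actin", "holding_pipette", hold); set("actin", "injection_pipette", tool)
  # ACP row
  set("acp", "acp", act)
  set("acp", "probe", tool); set("acp", "substrate", tool)
  set("acp", "holding_pipette", hold); set("acp", "injection_pipette", tool)
  # solvent (standard soft DPD fluid)
  for (sp in CYTO_SPECIES) set("solvent", sp, c(25, 4.5, 1))
  # rigid tools never interact among themselves (all frozen anyway)
  for (t1 in c("probe", "substrate", "holding_pipette", "injection_pipette"))
    for (t2 in c("probe", "substrate", "holding_pipette", "injection_pipette"))
      set(t1, t2, c(0, 0, 0))

  pp <- structure(list(a = a, gamma = g, rc = rc, kBT = kBT),
                  class = "pair_params")
  if (!is.null(overrides)) {
    for (ov in overrides) {
      pp$a[ov$i, ov$j] <- pp$a[ov$j, ov$i] <- ov$a
      pp$gamma[ov$i, ov$j] <- pp$gamma[ov$j, ov$i] <- ov$gamma
      pp$rc[ov$i, ov$j] <- pp$rc[ov$j, ov$i] <- ov$rc
    }
  }
  validate_pair_params(pp)
  pp
}

#' Validate a pair-parameter table
#'
#' Checks symmetry, non-negativity, and (when a user supplies an explicit
#' \code{sigma}) the fluctuation-dissipation constraint
#' \code{sigma^2 = 2 gamma kBT}.
#'
#' @param pp a \code{pair_params} object.
#' @param sigma optional matrix of random-force coefficients to check
#'   against \code{2 gamma kBT}.
#' @return \code{pp}, invisibly; errors on violation.
#' @export
validate_pair_params <- function(pp, sigma = NULL) {
  stopifnot(inherits(pp, "pair_params"))
  for (nm in c("a", "gamma", "rc")) {
    m <- pp[[nm]]
    if (!isTRUE(all.equal(m, t(m))))
      stop("pair_params$", nm, " is not symmetric in species order")
    if (any(m < 0)) stop("pair_params$", nm, " has negative entries")
  }
  if (pp$kBT <= 0) stop("kBT must be positive")
  if (!is.null(sigma)) {
    want <- sqrt(2 * pp$gamma * pp$kBT)
    if (any(abs(sigma - want) > 1e-9 * (1 + want)))
      stop("sigma inconsistent with fluctuation-dissipation: ",
           "sigma^2 must equal 2*gamma*kBT")
  }
  invisible(pp)
}

#' Random-force coefficient implied by the fluctuation-dissipation theorem
#'
#' @param gamma friction coefficient (scalar or matrix).
#' @param kBT energy scale.
#' @return \code{sqrt(2 * gamma * kBT)}.
#' @export
fd_sigma <- function(gamma, kBT = 1) sqrt(2 * gamma * kBT)

#' @export
print.pair_params <- function(x, ...) {
  cat("DPD pair parameters (a / gamma / r_c), kBT =", x$kBT, "\n")
  used <- which(x$rc > 0, arr.ind = TRUE)
  used <- used[used[, 1] <= used[, 2], , drop = FALSE]
  for (k in seq_len(nrow(used))) {
    i <- used[k, 1]; j <- used[k, 2]
    cat(sprintf("  %-18s %-18s %6g / %4g / %g\n",
                CYTO_SPECIES[i], CYTO_SPECIES[j],
                x$a[i, j], x$gamma[i, j], x$rc[i, j]))
  }
  invisible(x)
}
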