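#' Write an extended-XYZ trajectory frame
#'
#' One frame per call: count line, comment line, then
#' \code{species x y z} records at full double precision.
#'
#' @param sys a \code{particle_system} (or list with \code{pos},
#'   \code{types}).
#' @param path output file.
#' @param comment comment line content.
#' @param append append as an additional frame.
#' @export
write_xyz <- function(sys, path, comment = "", append = FALSE) {
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  writeLines(as.character(nrow(sys$pos)), con)
  writeLines(comment, con)
  writeLines(sprintf("%s %.17g %.17g %.17g", sys$types,
                     sys$pos[, 1], sys$pos[, 2], sys$pos[, 3]), con)
  invisible(path)
}

#' Read an extended-XYZ file (first frame)
#'
#' @param path XYZ file.
#' @return list with \code{pos} (n x 3), \code{types}, \code{comment}.
#' @export
read_xyz <- function(path) {
  ln <- readLines(path)
  n <- as.integer(ln[1])
  comment <- ln[2]
  parts <- strsplit(trimws(ln[3:(2 + n)]), "\\s+")
  types <- vapply(parts, `[`, character(1), 1)
  pos <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  list(pos = pos, types = types, comment = comment)
}

#' Full default configuration
#'
#' Every tunable of the simulator with its shipped default, grouped by
#' section: box/integrator, pair tables, membrane, cytoskeleton, and the
#' assay protocols.  This is the document \code{\link{load_config}}
#' validates user files against.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  pp <- pair_params()
  list(
    integrator = list(dt = 0.005, kBT = 1, lambda = 0.5, rng_seed = 1),
    box = list(lengths = c(28, 28, 28), periodic = c(FALSE, FALSE, FALSE)),
    pairs = list(a = pp$a, gamma = pp$gamma, rc = pp$rc),
    membrane = list(radius = 8, level = 3, mu0 = 100, x0 = 0.45, m = 2,
                    kbending = 65, ka = 7.5e3, kv = 7.5e3, kd = 300,
                    gamma_bond = 45, eq6_variant = "printed"),
    cytoskeleton = list(Na = 2698, Naf = c(3, 11), n_acp = 1000,
                        kbond = 8e4, kangle = 350, kacp = 8e3, kb = 550,
                        kt = 470, kon0 = 26e-4, koff0 = 26e-4,
                        sigma_on = c(3.5e-4, 1e-4),
                        sigma_off = c(3.5e-4, 1e-4),
                        don = 0.25, doff = 0.25, acp_l0 = 0.2,
                        bond_r0 = 0.25, bind_every = 10),
    rheology = list(n_track = 40, tracer_radius = NA, gamma0 = 0.02,
                    cycles = 10, plate_fraction = 0.05, discard_cycles = 2),
    indentation = list(half_angle_deg = 18, speed = 0.05, nu = 0.5,
                       window = c(0.4, 0.8)),
    microinjection = list(holding_radius = 1.6, injection_radius = 0.6,
                          speeds = c(0.5, 1.5, 2.5),
                          speed_labels_um_s = c(2000, 6000, 10000),
                          aspiration_magnitude = 0.6, rupture_factor = 2))
}

#' Load and validate a YAML configuration
#'
#' Reads a (possibly partial) YAML document, rejects unknown keys, merges
#' it over the shipped defaults and validates the physical constraints
#' (positive dt/kBT, 0 < x0 < 1, symmetric pair tables, and -- when the
#' user supplies an explicit \code{sigma} table -- the
#' fluctuation-dissipation relation sigma^2 = 2 gamma kBT).
#'
#' @param path YAML file; \code{NULL} returns the pure defaults.
#' @return validated configuration list (class \code{cytomech_config}).
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- .merge_config(cfg, user, path = "")
    if (!is.null(user$pairs$sigma)) {
      g <- matrix(unlist(cfg$pairs$gamma), nrow(cfg$pairs$gamma))
      sig <- matrix(unlist(user$pairs$sigma), nrow(g), ncol(g))
      want <- sqrt(2 * g * cfg$integrator$kBT)
      if (any(abs(sig - want) > 1e-9 * (1 + want)))
        stop("config: pairs$sigma violates sigma^2 = 2*gamma*kBT")
    }
  }
  with(cfg$integrator, {
    if (dt <= 0) stop("config: integrator$dt must be positive")
    if (kBT <= 0) stop("config: integrator$kBT must be positive")
  })
  if (cfg$membrane$x0 <= 0 || cfg$membrane$x0 >= 1)
    stop("config: membrane$x0 must lie in (0, 1)")
  a <- as.matrix(cfg$pairs$a)
  if (!isTRUE(all.equal(a, t(a)))) stop("config: pairs$a must be symmetric")
  structure(cfg, class = "cytomech_config")
}

.merge_config <- function(base, user, path) {
  for (nm in names(user)) {
    if (nm == "sigma" && path == "$pairs") next  # validated, not stored
    if (!nm %in% names(base))
      stop("config: unknown key '", sub("^\\$", "", paste0(path, "$", nm)), "'")
    if (is.list(base[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(base[[nm]])))
      base[[nm]] <- .merge_config(base[[nm]], user[[nm]],
                                  paste0(path, "$", nm))
    else
      base[[nm]] <- if (is.matrix(base[[nm]]))
        matrix(unlist(user[[nm]]), nrow(base[[nm]]),
               dimnames = dimnames(base[[nm]])) else user[[nm]]
  }
  base
}

#' Dump a configuration to YAML
#'
#' Round-trips with \code{\link{load_config}}.
#'
#' @param cfg configuration list; \code{path} output file.
#' @export
dump_config <- function(cfg, path) {
  cfg <- unclass(cfg)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Generate deterministic desk-scale test fixtures
#'
#' Small, fully reproducible inputs for the analysis modules:
#' \describe{
#'   \item{dpd_fluid}{random solvent cube (XYZ).}
#'   \item{small_membrane}{level-1 icosphere mesh (OFF).}
#'   \item{toy_network}{small filament network (XYZ, species actin/acp).}
#'   \item{affine_cloud_pair}{reference cloud plus its image under a stated
#'     affine map; ground-truth strain included.}
#'   \item{synthetic_msd}{power-law MSD curve with known exponent (CSV).}
#'   \item{synthetic_stress}{sinusoidal stress record with known amplitude
#'     and phase (CSV).}
#' }
#'
#' @param kind fixture kind (see above).
#' @param size scale knob (particle count or series length).
#' @param seed RNG seed; identical seeds give byte-identical files.
#' @param dir output directory.
#' @return named list of written file paths (plus ground-truth values as
#'   attribute \code{"truth"} where applicable).
#' @export
generate_fixture <- function(kind, size = 100, seed = 1, dir = tempdir()) {
  kinds <- c("dpd_fluid", "small_membrane", "toy_network",
             "affine_cloud_pair", "synthetic_msd", "synthetic_stress")
  if (!kind %in% kinds)
    stop("unknown fixture kind '", kind, "'; available: ",
         paste(kinds, collapse = ", "))
  set.seed(seed)
  out <- list()
  truth <- NULL
  if (kind == "dpd_fluid") {
    sys <- dpd_fluid(L = max(3, round(size^(1 / 3))), seed = seed)
    out$xyz <- file.path(dir, sprintf("dpd_fluid_%d.xyz", seed))
    write_xyz(sys, out$xyz, comment = sprintf("seed=%d", seed))
  } else if (kind == "small_membrane") {
    mesh <- build_membrane_mesh(radius = 4, level = 1)
    out$off <- file.path(dir, sprintf("small_membrane_%d.off", seed))
    write_off(mesh, out$off)
  } else if (kind == "toy_network") {
    net <- generate_filament_network(
      Na = size, n_acp = max(4, size %/% 3),
      region = list(kind = "box", box = c(5, 5, 5)), seed = seed)
    sys <- particle_system(
      pos = rbind(net$actin_pos, net$acp_pos),
      types = c(rep("actin", nrow(net$actin_pos)),
                rep("acp", nrow(net$acp_pos))),
      box = c(5, 5, 5))
    out$xyz <- file.path(dir, sprintf("toy_network_%d.xyz", seed))
    write_xyz(sys, out$xyz, comment = sprintf("seed=%d", seed))
  } else if (kind == "affine_cloud_pair") {
    ref <- matrix(runif(3 * size, 0, 5), size, 3)
    A <- diag(c(1.0, 1.1, 1.0))            # 10% stretch along y
    cur <- ref %*% t(A)
    out$ref <- file.path(dir, sprintf("cloud_ref_%d.csv", seed))
    out$cur <- file.path(dir, sprintf("cloud_cur_%d.csv", seed))
    out$truth <- file.path(dir, sprintf("cloud_truth_%d.csv", seed))
    .write_cloud_csv(ref, out$ref)
    .write_cloud_csv(cur, out$cur)
    truth <- list(A = A, strain_y = A[2, 2] - 1)
    write.csv(data.frame(axis = "y", strain = A[2, 2] - 1),
              out$truth, row.names = FALSE)
  } else if (kind == "synthetic_msd") {
    expo <- 0.85
    t <- exp(seq(log(0.05), log(50), length.out = size))
    out$csv <- file.path(dir, sprintf("synthetic_msd_%d.csv", seed))
    write.csv(data.frame(t = t, msd = 0.1 * t^expo), out$csv,
              row.names = FALSE)
    truth <- list(exponent = expo)
  } else if (kind == "synthetic_stress") {
    fs <- 0.5; amp <- 2; phi <- 0.3
    t <- seq(0, 10 / fs, length.out = size * 10)
    out$csv <- file.path(dir, sprintf("synthetic_stress_%d.csv", seed))
    write.csv(data.frame(time = t,
                         strain = 0.02 * sin(2 * pi * fs * t),
                         stress = amp * sin(2 * pi * fs * t + phi)),
              out$csv, row.names = FALSE)
    truth <- list(fs = fs, amplitude = amp, phase = phi)
  }
  attr(out, "truth") <- truth
  out
}

.write_cloud_csv <- function(x, path) {
  df <- data.frame(id = seq_len(nrow(x)), x = x[, 1], y = x[, 2],
                   z = if (ncol(x) > 2) x[, 3] else 0)
  write.csv(df, path, row.names = FALSE)
}

#' Read a point-cloud CSV (id, x, y, z)
#'
#' @param path CSV with columns id, x, y[, z].
#' @return matrix ordered by id.
#' @export
read_cloud_csv <- function(path) {
  d <- read.csv(path)
  d <- d[order(d$id), ]
  as.matrix(d[, intersect(c("x", "y", "z"), names(d))])
}

#' Write observables with a manifest-style header comment
#'
#' @param obs data frame; \code{path} output CSV; \code{seed} RNG seed;
#'   \code{extra} named character vector of additional header fields.
#' @export
write_observables <- function(obs, path, seed, extra = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(sprintf("# cytomech observables; seed=%d", seed),
           if (!is.null(extra)) sprintf("# %s=%s", names(extra), extra))
  writeLines(hdr, con)
  write.csv(obs, con, row.names = FALSE)
  invisible(path)
}
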