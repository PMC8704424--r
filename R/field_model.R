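# Static volume-conductor model of a current-injecting disk electrode.
#
# The quasi-static potential in a homogeneous ohmic medium obeys
# div(sigma grad V) = 0 with E = -grad V. Two disk boundary conditions are
# supported: uniform current density over the disk (the default) and an
# equipotential (primary-distribution) disk. Closed-form accessors serve as
# oracles for the axisymmetric finite-volume solver.

#' Volume-conductor model configuration
#'
#' @param electrode An [electrode_geometry()] (disk diameter in um).
#' @param sigma_S_per_m Medium conductivity (S/m); 0.2 is a standard value
#'   for retinal tissue.
#' @param domain `"sphere"` (grounded shell, default diameter 18 mm),
#'   `"halfspace"` (disk on an insulating plane, fields doubled) or
#'   `"fullspace"` (disk radiating into an unbounded medium).
#' @param domain_diameter_mm Sphere diameter (sphere mode) or twice the
#'   finite-volume domain extent (other modes).
#' @param bc Disk boundary condition: `"uniform_j"` (fixed current density on
#'   the disk surface) or `"equipotential"`.
#' @param return_distance_mm,return_diameter_um Return-electrode placement;
#'   recorded for provenance, the return is treated as the grounded far
#'   boundary (it is >3 orders of magnitude farther than the disk radius).
#' @return Object of class `volume_conductor`.
#' @export
volume_conductor <- function(electrode = electrode_geometry(10),
                             sigma_S_per_m = 0.2,
                             domain = c("sphere", "halfspace", "fullspace"),
                             domain_diameter_mm = 18,
                             bc = c("uniform_j", "equipotential"),
                             return_distance_mm = 7.5,
                             return_diameter_um = 200) {
  domain <- match.arg(domain)
  bc <- match.arg(bc)
  if (sigma_S_per_m <= 0) stop_stim("conductivity must be > 0", "invalid_parameter")
  a_m <- electrode$diameter_um * 1e-6 / 2
  if (domain_diameter_mm * 1e-3 / 2 <= 2 * a_m) {
    stop_stim("electrode does not fit inside the domain", "invalid_geometry")
  }
  structure(list(electrode = electrode, sigma_S_per_m = sigma_S_per_m,
                 domain = domain, domain_diameter_mm = domain_diameter_mm,
                 bc = bc, return_distance_mm = return_distance_mm,
                 return_diameter_um = return_diameter_um),
            class = "volume_conductor")
}

#' Activation criterion for extracellular stimulation
#'
#' @param e_threshold_V_per_m Minimum field magnitude assumed to drive
#'   stimulation (V/m); 1000 V/m is the conventional criterion.
#' @param pulse_width_s Phase width used to convert between charge and
#'   current (s), default 1 ms.
#' @export
activation_criterion <- function(e_threshold_V_per_m = 1000, pulse_width_s = 1e-3) {
  if (e_threshold_V_per_m <= 0) stop_stim("field threshold must be > 0", "invalid_parameter")
  structure(list(e_threshold_V_per_m = e_threshold_V_per_m,
                 pulse_width_s = pulse_width_s),
            class = "activation_criterion")
}

# geometry multiplier: half-space concentrates all current into one side
.domain_factor <- function(model) if (model$domain == "halfspace") 2 else 1

#' Closed-form disk-source potential and field
#'
#' Analytic solution of the static volume-conductor problem for a disk
#' source, used both directly and as the oracle for [solve_field()]. For the
#' uniform-current-density disk in full space the on-axis potential is
#' V(z) = I/(2 pi sigma a^2) (sqrt(z^2+a^2) - z) with axial field
#' E_z = I/(2 pi sigma a^2) (1 - z/sqrt(z^2+a^2)); off-axis values follow by
#' integrating the surface source with a complete-elliptic-integral kernel.
#' The equipotential disk uses the oblate-spheroidal solution. Half-space
#' doubles both; the spherical domain is treated as full space (the grounded
#' shell is >1e3 disk radii away).
#'
#' @param model A [volume_conductor()].
#' @param I_A Injected current (A).
#' @param z_um On-axis distances from the electrode plane (um), vectorised.
#' @param r_um Radial offsets (um); scalar or same length as `z_um`.
#' @return data.frame with columns `r_um`, `z_um`, `V_V`, `E_z_V_per_m`,
#'   `E_mag_V_per_m`.
#' @export
analytic_disk_field <- function(model, I_A, z_um, r_um = 0) {
  stopifnot(inherits(model, "volume_conductor"))
  n <- max(length(z_um), length(r_um))
  z <- rep_len(z_um, n) * 1e-6
  r <- abs(rep_len(r_um, n)) * 1e-6   # axisymmetric: field depends on |r|
  if (any(z < 0)) stop_stim("z must be >= 0 (conductor side)", "domain")
  a <- model$electrode$diameter_um * 1e-6 / 2
  if (any(abs(r - a) < 1e-12 & z < 1e-12)) {
    stop_stim("field is singular on the disk edge", "domain")
  }
  sg <- model$sigma_S_per_m
  f <- .domain_factor(model)

  if (I_A == 0) {
    return(data.frame(r_um = r * 1e6, z_um = z * 1e6, V_V = 0,
                      E_z_V_per_m = 0, E_mag_V_per_m = 0))
  }

  if (model$bc == "uniform_j") {
    on_axis <- abs(r) < 1e-12
    V <- Ez <- Emag <- numeric(n)
    c0 <- f * I_A / (2 * pi * sg * a^2)
    V[on_axis]  <- c0 * (sqrt(z[on_axis]^2 + a^2) - z[on_axis])
    Ez[on_axis] <- c0 * (1 - z[on_axis] / sqrt(z[on_axis]^2 + a^2))
    Emag[on_axis] <- abs(Ez[on_axis])
    if (any(!on_axis)) {
      idx <- which(!on_axis)
      Vfun <- function(rr, zz) .uniform_j_offaxis_V(rr, zz, a, sg, I_A) * f
      for (i in idx) {
        V[i] <- Vfun(r[i], z[i])
        h <- 1e-3 * a
        Ez[i] <- -(Vfun(r[i], z[i] + h) - Vfun(r[i], max(z[i] - h, 0))) /
          (h + min(z[i], h))
        Er <- -(Vfun(r[i] + h, z[i]) - Vfun(max(r[i] - h, 0), z[i])) /
          (h + min(r[i], h))
        Emag[i] <- sqrt(Ez[i]^2 + Er^2)
      }
    }
  } else { # equipotential disk (oblate-spheroidal primary distribution)
    v0 <- f * I_A / (8 * sg * a)
    on_axis <- abs(r) < 1e-12
    V <- Ez <- Emag <- numeric(n)
    V[on_axis]  <- (2 * v0 / pi) * asin(a / sqrt(a^2 + z[on_axis]^2))
    Ez[on_axis] <- (2 * v0 / pi) * a / (a^2 + z[on_axis]^2)
    Emag[on_axis] <- abs(Ez[on_axis])
    if (any(!on_axis)) {
      idx <- which(!on_axis)
      for (i in idx) {
        l1 <- sqrt((r[i] - a)^2 + z[i]^2); l2 <- sqrt((r[i] + a)^2 + z[i]^2)
        V[i] <- (2 * v0 / pi) * asin(2 * a / (l1 + l2))
        h <- 1e-3 * a
        Vf <- function(rr, zz) {
          L1 <- sqrt((rr - a)^2 + zz^2); L2 <- sqrt((rr + a)^2 + zz^2)
          (2 * v0 / pi) * asin(2 * a / (L1 + L2))
        }
        Ez[i] <- -(Vf(r[i], z[i] + h) - Vf(r[i], max(z[i] - h, 0))) / (h + min(z[i], h))
        Er <- -(Vf(r[i] + h, z[i]) - Vf(max(r[i] - h, 0), z[i])) / (h + min(r[i], h))
        Emag[i] <- sqrt(Ez[i]^2 + Er^2)
      }
    }
  }
  data.frame(r_um = r * 1e6, z_um = z * 1e6, V_V = V,
             E_z_V_per_m = Ez, E_mag_V_per_m = Emag)
}

# Off-axis potential of a uniform-current-density disk in full space:
# V(r,z) = (J / 4 pi sigma) * int_0^a r' [4 K(m) / sqrt((r+r')^2+z^2)] dr',
# m = 4 r r' / ((r+r')^2 + z^2). Radial quadrature via integrate().
.uniform_j_offaxis_V <- function(r, z, a, sigma, I_A) {
  J <- I_A / (pi * a^2)
  kern <- function(rp) {
    m <- 4 * r * rp / ((r + rp)^2 + z^2)
    K <- vapply(m, function(mm) pracma::ellipke(min(mm, 1 - 1e-12))$k, numeric(1))
    rp * 4 * K / sqrt((r + rp)^2 + z^2)
  }
  (J / (4 * pi * sigma)) * stats::integrate(kern, 0, a, rel.tol = 1e-8)$value
}

#' Graded axisymmetric grid specification
#'
#' Node spacing is uniform (`h0`) out to `fine_extent` times the disk radius
#' in both r and z, then grows geometrically by `grow` per interval to the
#' domain edge. The edge singularity of the disk demands the local
#' refinement; the far field tolerates coarse cells.
#'
#' @param model A [volume_conductor()].
#' @param refine Refinement level; level k halves `h0` and takes the square
#'   root of `grow` relative to level 1.
#' @param h0_um Base fine spacing (um); default disk radius / 16.
#' @param grow Geometric growth ratio of coarse intervals (default 1.2).
#' @param fine_extent Fine-region extent in disk radii (default 2).
#' @param extent_mm Domain extent (mm); defaults to the model's domain radius.
#' @return List with node vectors `r_um`, `z_um`.
#' @export
field_grid <- function(model, refine = 1, h0_um = NULL, grow = 1.2,
                       fine_extent = 2, extent_mm = NULL) {
  a_um <- model$electrode$diameter_um / 2
  if (is.null(h0_um)) h0_um <- a_um / 16
  h <- h0_um / 2^(refine - 1)
  g <- grow^(1 / 2^(refine - 1))
  if (is.null(extent_mm)) extent_mm <- model$domain_diameter_mm / 2
  ext_um <- extent_mm * 1e3

  axis_nodes <- function() {
    x <- seq(0, fine_extent * a_um, by = h)
    step <- h
    while (x[length(x)] < ext_um) {
      step <- step * g
      x <- c(x, x[length(x)] + step)
    }
    x[length(x)] <- ext_um
    x
  }
  list(r_um = axis_nodes(), z_um = axis_nodes())
}

#' Finite-volume solution of the volume-conductor problem
#'
#' Solves div(sigma grad V) = 0 on an axisymmetric (r, z) tensor grid with a
#' Neumann current-density flux J = I / (pi a^2) over the disk at z = 0,
#' zero flux on the rest of the insulating plane, and a Dirichlet far
#' boundary: V = 0 on the grounded shell in sphere mode, or the asymptotic
#' point-source potential at the domain edge in halfspace/fullspace mode
#' (an open-boundary condition; a hard zero at finite range would bias the
#' near field by O(z / R)). Full-space and sphere solutions exploit the
#' mirror symmetry of the disk source by solving one half with I/2.
#' Conservative finite-volume fluxes; direct sparse solve.
#'
#' @param model A [volume_conductor()] (bc must be `"uniform_j"`).
#' @param I_A Injected current (A).
#' @param grid A [field_grid()] specification.
#' @return Object of class `field_solution`: node vectors `r_um`, `z_um`,
#'   matrices `V_V`, `E_r_V_per_m`, `E_z_V_per_m`, `E_mag_V_per_m`
#'   (rows = r, cols = z), plus `I_A`, `J_A_m2`, `model`, `grid`.
#' @export
solve_field <- function(model, I_A, grid = field_grid(model)) {
  stopifnot(inherits(model, "volume_conductor"))
  if (model$bc != "uniform_j") {
    stop_stim("the finite-volume solver implements the uniform_j disk condition",
              "invalid_parameter")
  }
  r <- grid$r_um * 1e-6; z <- grid$z_um * 1e-6
  nr <- length(r); nz <- length(z)
  a <- model$electrode$diameter_um * 1e-6 / 2
  if (sum(r <= a) < 10L) {
    warn_stim("grid resolves the electrode radius with <10 nodes", "resolution")
  }
  sg <- model$sigma_S_per_m
  f <- .domain_factor(model)
  I_inj <- if (model$domain == "halfspace") I_A else I_A / 2

  # control-volume radial bounds per node
  rL <- c(0, (r[-nr] + r[-1]) / 2)
  rR <- c((r[-nr] + r[-1]) / 2, r[nr])
  zL <- c(z[1], (z[-nz] + z[-1]) / 2)
  zR <- c((z[-nz] + z[-1]) / 2, z[nz])

  # unknowns: all nodes except the Dirichlet layers i = nr, j = nz
  ni <- nr - 1L; nj <- nz - 1L
  idx <- function(i, j) (j - 1L) * ni + i
  N <- ni * nj

  dir_val <- function(rb, zb) {
    if (model$domain == "sphere") return(0 * rb * zb)
    # asymptotic point-source value; f = 2 gives the half-space monopole
    d <- pmax(sqrt(rb^2 + zb^2), a)
    f * I_A / (4 * pi * sg * d)
  }

  rhs <- numeric(N)
  diag_acc <- numeric(N)

  # assemble via vectors: per-direction face conductances
  # radial faces between (i, j) and (i+1, j), i = 1..nr-1
  rf <- (r[-nr] + r[-1]) / 2
  dr <- diff(r)
  # axial faces between (i, j) and (i, j+1), j = 1..nz-1
  dz <- diff(z)
  annul <- pi * (rR^2 - rL^2)             # per-node annular area (length nr)

  ent_i <- integer(0); ent_j <- integer(0); ent_x <- numeric(0)
  add <- function(ei, ej, ex) {
    ent_i <<- c(ent_i, ei); ent_j <<- c(ent_j, ej); ent_x <<- c(ent_x, ex)
  }

  # radial connections
  for (j in seq_len(nj)) {
    hz <- zR[j] - zL[j]
    G <- sg * 2 * pi * rf * hz / dr       # length nr-1
    # interior pairs i -> i+1 where both unknown (i+1 <= ni)
    i_int <- seq_len(ni - 1L)
    p <- idx(i_int, j); q <- idx(i_int + 1L, j)
    add(p, q, -G[i_int]); add(q, p, -G[i_int])
    k1 <- idx(seq_len(ni), j)
    diag_acc[k1] <- diag_acc[k1] +
      c(G[seq_len(ni - 1L)], 0) +                      # face to the right within unknowns
      c(0, G[seq_len(ni - 1L)])                        # face to the left
    # face from i = ni to the Dirichlet node i = nr
    Gb <- G[ni]
    kb <- idx(ni, j)
    diag_acc[kb] <- diag_acc[kb] + Gb
    rhs[kb] <- rhs[kb] + Gb * dir_val(r[nr], z[j])
  }

  # axial connections
  for (i in seq_len(ni)) {
    G <- sg * annul[i] / dz               # length nz-1
    j_int <- seq_len(nj - 1L)
    p <- idx(i, j_int); q <- idx(i, j_int + 1L)
    add(p, q, -G[j_int]); add(q, p, -G[j_int])
    k1 <- idx(i, seq_len(nj))
    diag_acc[k1] <- diag_acc[k1] + c(G[seq_len(nj - 1L)], 0) + c(0, G[seq_len(nj - 1L)])
    Gb <- G[nj]
    kb <- idx(i, nj)
    diag_acc[kb] <- diag_acc[kb] + Gb
    rhs[kb] <- rhs[kb] + Gb * dir_val(r[i], z[nz])
  }

  # Neumann injection on the disk (z = 0 row): J over covered annulus
  Jd <- I_inj / (pi * a^2)
  cov <- pi * (pmin(rR, a)^2 - pmin(rL, a)^2)
  for (i in seq_len(ni)) {
    if (cov[i] > 0) rhs[idx(i, 1L)] <- rhs[idx(i, 1L)] + Jd * cov[i]
  }

  A <- Matrix::sparseMatrix(i = c(ent_i, seq_len(N)), j = c(ent_j, seq_len(N)),
                            x = c(ent_x, diag_acc), dims = c(N, N))
  Vvec <- as.numeric(Matrix::solve(A, rhs))
  res <- sqrt(sum((as.numeric(A %*% Vvec) - rhs)^2)) / max(sqrt(sum(rhs^2)), 1e-300)
  if (res > 1e-8) stop_stim(sprintf("linear solve residual %.2e too large", res), "solver")

  V <- matrix(0, nr, nz)
  V[seq_len(ni), seq_len(nj)] <- matrix(Vvec, ni, nj)
  # Dirichlet layers
  V[nr, ] <- dir_val(r[nr], z)
  V[, nz] <- dir_val(r, z[nz])

  grad1 <- function(x, M, along) {
    # central differences on a nonuniform grid, one-sided at ends
    n <- length(x); D <- M * 0
    h1 <- x[2] - x[1]; hn <- x[n] - x[n - 1]
    if (along == 1) {
      for (k in 2:(n - 1)) {
        hm <- x[k] - x[k - 1]; hp <- x[k + 1] - x[k]
        D[k, ] <- (hm^2 * M[k + 1, ] - hp^2 * M[k - 1, ] + (hp^2 - hm^2) * M[k, ]) /
          (hm * hp * (hm + hp))
      }
      D[1, ] <- (M[2, ] - M[1, ]) / h1
      D[n, ] <- (M[n, ] - M[n - 1, ]) / hn
    } else {
      for (k in 2:(n - 1)) {
        hm <- x[k] - x[k - 1]; hp <- x[k + 1] - x[k]
        D[, k] <- (hm^2 * M[, k + 1] - hp^2 * M[, k - 1] + (hp^2 - hm^2) * M[, k]) /
          (hm * hp * (hm + hp))
      }
      D[, 1] <- (M[, 2] - M[, 1]) / h1
      D[, n] <- (M[, n] - M[, n - 1]) / hn
    }
    D
  }
  Er <- -grad1(r, V, 1)
  Ez <- -grad1(z, V, 2)

  structure(list(r_um = grid$r_um, z_um = grid$z_um, V_V = V,
                 E_r_V_per_m = Er, E_z_V_per_m = Ez,
                 E_mag_V_per_m = sqrt(Er^2 + Ez^2),
                 I_A = I_A, J_A_m2 = I_A / (pi * a^2),
                 model = model, grid = grid, residual = res),
            class = "field_solution")
}

#' On-axis profile of a field solution
#'
#' @param solution A [solve_field()] result.
#' @return data.frame with `z_um`, `V_V`, `E_mag_V_per_m`.
#' @export
on_axis_profile <- function(solution) {
  stopifnot(inherits(solution, "field_solution"))
  data.frame(z_um = solution$z_um, V_V = solution$V_V[1, ],
             E_mag_V_per_m = solution$E_mag_V_per_m[1, ])
}

#' On-axis activation depth at a field criterion
#'
#' Largest on-axis distance from the electrode plane at which the field
#' magnitude still meets the threshold. For the uniform-current-density disk
#' the inversion is closed-form; the equipotential variant is solved by
#' root bisection; a gridded [solve_field()] result is interpolated.
#'
#' @param model A [volume_conductor()].
#' @param I_A Injected current (A).
#' @param criterion An [activation_criterion()].
#' @param solution Optional [solve_field()] result to interrogate instead of
#'   the closed form.
#' @return List: `depth_um`, `status` ("ok" or "subthreshold").
#' @export
activation_depth <- function(model, I_A, criterion = activation_criterion(),
                             solution = NULL) {
  eth <- criterion$e_threshold_V_per_m
  if (!is.null(solution)) {
    prof <- on_axis_profile(solution)
    above <- prof$E_mag_V_per_m >= eth
    if (!any(above)) return(list(depth_um = 0, status = "subthreshold"))
    k <- max(which(above))
    if (k == nrow(prof)) return(list(depth_um = prof$z_um[k], status = "ok"))
    z0 <- prof$z_um[k]; z1 <- prof$z_um[k + 1L]
    e0 <- prof$E_mag_V_per_m[k]; e1 <- prof$E_mag_V_per_m[k + 1L]
    return(list(depth_um = z0 + (eth - e0) / (e1 - e0) * (z1 - z0), status = "ok"))
  }

  a <- model$electrode$diameter_um * 1e-6 / 2
  sg <- model$sigma_S_per_m
  f <- .domain_factor(model)
  if (I_A <= 0) return(list(depth_um = 0, status = "subthreshold"))

  if (model$bc == "uniform_j") {
    k <- eth * 2 * pi * sg * a^2 / (f * I_A)  # normalised threshold
    if (k >= 1) return(list(depth_um = 0, status = "subthreshold"))
    z <- a * (1 - k) / sqrt(k * (2 - k))
    return(list(depth_um = z * 1e6, status = "ok"))
  }
  # equipotential: E_z(z) = (2 v0 / pi) a / (a^2 + z^2)
  v0 <- f * I_A / (8 * sg * a)
  e0 <- (2 * v0 / pi) / a
  if (e0 < eth) return(list(depth_um = 0, status = "subthreshold"))
  z <- sqrt((2 * v0 / pi) * a / eth - a^2)
  list(depth_um = z * 1e6, status = "ok")
}

#' Current required to reach the field criterion at a depth
#'
#' By linearity of the volume-conductor problem, the required current is the
#' threshold divided by the on-axis field per unit current at that depth.
#'
#' @param z_um On-axis depth(s) from the electrode plane (um), vectorised.
#' @param model A [volume_conductor()].
#' @param criterion An [activation_criterion()].
#' @return Current(s) in A.
#' @export
required_current <- function(z_um, model, criterion = activation_criterion()) {
  if (any(z_um < 0)) stop_stim("depth must be >= 0", "domain")
  e_unit <- analytic_disk_field(model, 1, z_um)$E_mag_V_per_m
  criterion$e_threshold_V_per_m / e_unit
}

#' Required-current curve truncated at the charge-injection limit
#'
#' Builds the current-vs-depth curve for a diameter and marks the reachable
#' segment: currents above the CIC-limited current for the phase width are
#' flagged unreachable.
#'
#' @param model A [volume_conductor()].
#' @param criterion An [activation_criterion()].
#' @param cic_mC_cm2 CIC density used for the charge limit.
#' @param z_um Depth grid (um).
#' @return data.frame `z_um`, `I_uA`, `within_cic`.
#' @export
required_current_curve <- function(model, criterion = activation_criterion(),
                                   cic_mC_cm2 = 3.3,
                                   z_um = seq(1, 100, by = 1)) {
  I_req <- required_current(z_um, model, criterion)
  q_nC <- max_injectable_charge(model$electrode, cic_mC_cm2)
  I_max <- q_nC * 1e-9 / criterion$pulse_width_s
  data.frame(z_um = z_um, I_uA = I_req * 1e6, within_cic = I_req <= I_max)
}
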