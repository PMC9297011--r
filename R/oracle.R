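#' Closed-form steady state of a 1-D water film
#'
#' A water film of thickness `L` separates a water-air interface (Robin
#' dissolution boundary, coefficient `alpha`, far-side saturation `Ceq`)
#' from a microbially reactive wall (first-order uptake `k_wall`). At steady
#' state the concentration profile is linear and the wall concentration has
#' the closed form \eqn{C_o = C_{eq}/(1 + k L/D + k/\alpha)}; this is
#' exactly the volumetric-average closure with equal interface and wall
#' areas, which is what makes the film the analytic anchor for the 2-D
#' solver and the closure alike.
#'
#' @param L film thickness (> 0).
#' @param alpha dissolution coefficient (> 0).
#' @param D aqueous diffusivity (> 0).
#' @param k_wall first-order wall uptake coefficient (>= 0).
#' @param Ceq interface saturation concentration (> 0).
#' @return list with `c0` (interface-side concentration), `Co` (wall
#'   concentration) and `flux` (`k_wall * Co`, per unit wall area).
#' @export
solve_film <- function(L, alpha, D, k_wall, Ceq) {
  for (nm in c("L", "alpha", "D", "k_wall", "Ceq")) .check_finite(get(nm), nm)
  if (any(c(L, alpha, D, Ceq) <= 0) || k_wall < 0)
    .stopf("film parameters must be positive (k_wall >= 0)")
  Co <- Ceq / (1 + k_wall * L / D + k_wall / alpha)
  list(c0 = Co * (1 + k_wall * L / D), Co = Co, flux = k_wall * Co)
}

#' Parse a pore-geometry text mask
#'
#' Masks are rectangular character grids: `#` solid (no-flux), `.` water,
#' `I` air cells whose faces with water are dissolution interfaces, `W`
#' solid cells whose faces with water are reactive walls. Lines may be
#' given directly or as a file path.
#'
#' @param x character vector of mask lines, or a path to a mask file.
#' @return character matrix (rows x columns) of single characters.
#' @export
read_geometry <- function(x) {
  if (length(x) == 1 && file.exists(x)) x <- readLines(x)
  x <- x[nzchar(x)]
  if (length(x) == 0) .stopf("empty geometry mask")
  w <- unique(nchar(x))
  if (length(w) != 1) .stopf("geometry mask rows must have equal width")
  m <- do.call(rbind, strsplit(x, ""))
  bad <- setdiff(unique(as.vector(m)), c("#", ".", "I", "W"))
  if (length(bad) > 0)
    .stopf("invalid mask characters: %s", paste(bad, collapse = " "))
  m
}

#' Define a 2-D pore-scale reaction-diffusion problem
#'
#' @param mask character matrix from [read_geometry()] (or mask lines /
#'   file path, passed through it).
#' @param h grid spacing (> 0).
#' @param D aqueous diffusivity (> 0).
#' @param alpha dissolution coefficient at interface faces (> 0).
#' @param Ceq saturation concentration at interface faces (> 0).
#' @param k_wall wall uptake coefficient: a scalar, or a matrix the shape
#'   of `mask` giving per-cell coefficients for `W` cells (heterogeneous,
#'   "patchy" walls).
#' @return object of class `grid_problem`.
#' @export
grid_problem <- function(mask, h, D, alpha, Ceq, k_wall) {
  if (!is.matrix(mask)) mask <- read_geometry(mask)
  for (nm in c("h", "D", "alpha", "Ceq")) {
    .check_finite(get(nm), nm)
    if (get(nm) <= 0) .stopf("`%s` must be > 0", nm)
  }
  if (is.matrix(k_wall)) {
    if (!all(dim(k_wall) == dim(mask)))
      .stopf("matrix k_wall must match the mask dimensions")
  } else {
    .check_finite(k_wall, "k_wall")
    k_wall <- matrix(k_wall, nrow(mask), ncol(mask))
  }
  if (any(k_wall < 0)) .stopf("k_wall must be >= 0")
  if (!any(mask == ".")) .stopf("mask contains no water cells")
  if (!.mask_connected(mask)) .stopf("water domain must be connected")
  if (!any(.adjacent_faces(mask, "I"))) .stopf("mask has no interface face")
  if (!any(.adjacent_faces(mask, "W"))) .stopf("mask has no wall face")
  structure(list(mask = mask, h = h, D = D, alpha = alpha, Ceq = Ceq,
                 k_wall = k_wall), class = "grid_problem")
}

# TRUE where a water cell has at least one 4-neighbour of type `what`
.adjacent_faces <- function(mask, what) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix("#", nr + 2, nc + 2); pad[2:(nr + 1), 2:(nc + 1)] <- mask
  core <- pad[2:(nr + 1), 2:(nc + 1)] == "."
  core & (pad[1:nr, 2:(nc + 1)] == what | pad[3:(nr + 2), 2:(nc + 1)] == what |
            pad[2:(nr + 1), 1:nc] == what | pad[2:(nr + 1), 3:(nc + 2)] == what)
}

.mask_connected <- function(mask) {
  water <- which(mask == ".")
  if (length(water) <= 1) return(TRUE)
  nr <- nrow(mask)
  idx <- matrix(NA_integer_, nrow(mask), ncol(mask))
  idx[water] <- seq_along(water)
  seen <- logical(length(water)); seen[1] <- TRUE
  frontier <- water[1]
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (p in frontier) {
      i <- (p - 1) %% nr + 1; j <- (p - 1) %/% nr + 1
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ii <- i + d[1]; jj <- j + d[2]
        if (ii < 1 || ii > nr || jj < 1 || jj > ncol(mask)) next
        q <- idx[ii, jj]
        if (!is.na(q) && !seen[q]) { seen[q] <- TRUE; nxt <- c(nxt, (jj - 1) * nr + ii) }
      }
    }
    frontier <- nxt
  }
  all(seen)
}

#' Solve the steady reaction-diffusion problem on a pore-geometry grid
#'
#' Five-point finite-volume discretization of Laplace's equation for
#' dissolved O2 in the water cells. Interface faces carry the Robin
#' dissolution flux `alpha * (Ceq - c_face)` and wall faces the first-order
#' uptake flux `k_wall * c_face`; face concentrations are eliminated by a
#' half-cell (ghost) flux balance, which keeps the scheme exact for linear
#' profiles (so 1-D films are reproduced to machine precision). The sparse
#' linear system is solved directly.
#'
#' @param p a [grid_problem()].
#' @param tol relative conservation tolerance: the mismatch between total
#'   dissolution influx and total wall uptake must not exceed
#'   `tol * total_uptake`.
#' @return list with `field` (concentration matrix, `NA` outside water),
#'   `c0_bar` (mean interface-face concentration), `Co_bar` (mean wall-face
#'   concentration), `total_uptake`, `total_dissolution` (per unit depth),
#'   `L_bar` (mean hydraulic wall-to-interface distance, see Details) and
#'   geometry measures `interface_length`, `wall_length`, `water_area`.
#' @details The hydraulic distance reported for closure comparisons is the
#'   mean over wall-adjacent water cells of the shortest within-water path
#'   to an interface-adjacent water cell (breadth-first steps plus one,
#'   times the spacing), the discrete analogue of "average hydraulic
#'   distance between interfaces and microsites".
#' @export
solve_grid <- function(p, tol = 1e-10) {
  stopifnot(inherits(p, "grid_problem"))
  mask <- p$mask; h <- p$h; D <- p$D
  nr <- nrow(mask); nc <- ncol(mask)
  water <- which(mask == ".")
  idx <- matrix(NA_integer_, nr, nc); idx[water] <- seq_along(water)
  n <- length(water)

  ti <- integer(0); tj <- integer(0); tv <- numeric(0)
  diag_v <- numeric(n); rhs <- numeric(n)
  # face transfer coefficients (flux per unit face length), half-cell corrected
  g_int <- p$alpha * D / (D + p$alpha * h / 2)
  for (p1 in seq_along(water)) {
    cell <- water[p1]
    i <- (cell - 1) %% nr + 1; j <- (cell - 1) %/% nr + 1
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ii <- i + d[1]; jj <- j + d[2]
      ch <- if (ii < 1 || ii > nr || jj < 1 || jj > nc) "#" else mask[ii, jj]
      if (ch == ".") {
        q <- idx[ii, jj]
        # D * (c_q - c_p): conductance D (face length h over distance h)
        ti <- c(ti, p1); tj <- c(tj, q); tv <- c(tv, D)
        diag_v[p1] <- diag_v[p1] - D
      } else if (ch == "I") {
        diag_v[p1] <- diag_v[p1] - h * g_int
        rhs[p1] <- rhs[p1] - h * g_int * p$Ceq
      } else if (ch == "W") {
        kw <- p$k_wall[ii, jj]
        g_w <- kw * D / (D + kw * h / 2)
        diag_v[p1] <- diag_v[p1] - h * g_w
      } # "#": no flux
    }
  }
  A <- Matrix::sparseMatrix(i = c(ti, seq_len(n)), j = c(tj, seq_len(n)),
                            x = c(tv, diag_v), dims = c(n, n))
  c_vec <- as.numeric(Matrix::solve(A, rhs))

  field <- matrix(NA_real_, nr, nc); field[water] <- c_vec
  if (any(!is.finite(c_vec))) .stopf("grid solve failed (singular system?)")

  # face-resolved bookkeeping
  int_c <- numeric(0); wall_c <- numeric(0)
  uptake <- 0; dissolution <- 0; n_int <- 0; n_wall <- 0
  for (p1 in seq_along(water)) {
    cell <- water[p1]
    i <- (cell - 1) %% nr + 1; j <- (cell - 1) %/% nr + 1
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ii <- i + d[1]; jj <- j + d[2]
      ch <- if (ii < 1 || ii > nr || jj < 1 || jj > nc) "#" else mask[ii, jj]
      if (ch == "I") {
        f <- g_int * (p$Ceq - c_vec[p1])           # influx per face length
        dissolution <- dissolution + h * f
        int_c <- c(int_c, p$Ceq - f / p$alpha)     # face concentration
        n_int <- n_int + 1
      } else if (ch == "W") {
        kw <- p$k_wall[ii, jj]
        cf <- if (kw > 0) c_vec[p1] * D / (D + kw * h / 2) else c_vec[p1]
        uptake <- uptake + h * kw * cf
        wall_c <- c(wall_c, cf)
        n_wall <- n_wall + 1
      }
    }
  }
  if (uptake > 0 && abs(uptake - dissolution) > tol * uptake)
    .stopf("discrete conservation violated: uptake %g vs dissolution %g",
           uptake, dissolution)

  list(field = field,
       c0_bar = mean(int_c), Co_bar = mean(wall_c),
       total_uptake = uptake, total_dissolution = dissolution,
       L_bar = .mean_hydraulic_distance(mask) * h,
       interface_length = n_int * h, wall_length = n_wall * h,
       water_area = n * h^2,
       conservation_gap = if (uptake > 0) abs(uptake - dissolution) / uptake else 0)
}

# Mean over wall-adjacent water cells of (BFS steps to the nearest
# interface-adjacent water cell + 1); multiply by spacing for length units.
# The +1 accounts for the two half-cell legs from face to cell centre.
.mean_hydraulic_distance <- function(mask) {
  nr <- nrow(mask)
  water <- which(mask == ".")
  idx <- matrix(NA_integer_, nr, ncol(mask)); idx[water] <- seq_along(water)
  dist <- rep(NA_real_, length(water))
  src <- which(.adjacent_faces(mask, "I")[water])
  dist[src] <- 0
  frontier <- src
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (p1 in frontier) {
      cell <- water[p1]
      i <- (cell - 1) %% nr + 1; j <- (cell - 1) %/% nr + 1
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ii <- i + d[1]; jj <- j + d[2]
        if (ii < 1 || ii > nr || jj < 1 || jj > ncol(mask)) next
        q <- idx[ii, jj]
        if (!is.na(q) && is.na(dist[q])) { dist[q] <- dist[p1] + 1; nxt <- c(nxt, q) }
      }
    }
    frontier <- nxt
  }
  wall_adj <- .adjacent_faces(mask, "W")[water]
  mean(dist[wall_adj]) + 1
}

#' Refine a pore-geometry mask by an integer factor
#'
#' Each cell becomes an `r x r` block; the spacing of an equivalent
#' [grid_problem()] should be divided by `r`. Used for grid-convergence
#' studies.
#'
#' @param mask character matrix.
#' @param r integer refinement factor (>= 1).
#' @return refined character matrix.
#' @export
refine_mask <- function(mask, r) {
  r <- as.integer(r)
  if (r < 1) .stopf("refinement factor must be >= 1")
  mask[rep(seq_len(nrow(mask)), each = r), rep(seq_len(ncol(mask)), each = r)]
}

#' Relative error of the volumetric-average closure on an explicit geometry
#'
#' Solves the pore-scale problem by brute force, maps the geometry onto the
#' closure's inputs (interface and wall lengths per water area, mean
#' hydraulic distance), evaluates [steady_concentrations()], and reports
#' the signed relative difference in total O2 uptake,
#' `(closure - grid) / grid`. This quantifies the closure's two
#' approximations: the arithmetic-mean diffusion cross-section and the
#' uniform wall concentration.
#'
#' @param p a [grid_problem()] (uniform or patchy walls).
#' @param tol solver conservation tolerance, passed to [solve_grid()].
#' @return list with `error` (signed relative uptake error), `grid` (the
#'   [solve_grid()] report) and `closure` (the mapped closure solution).
#' @export
closure_error <- function(p, tol = 1e-10) {
  g <- solve_grid(p, tol = tol)
  V <- g$water_area
  A_wa <- g$interface_length / V
  A_ws <- g$wall_length / V
  # uptake-weighted mean wall coefficient (uniform walls: just k_wall)
  kws <- p$k_wall[.wall_cells(p$mask)]
  k_mean <- mean(kws)
  sc <- steady_concentrations(k_mean, p$alpha, p$D, g$L_bar, A_wa, A_ws,
                              p$Ceq)
  closure_uptake <- k_mean * g$wall_length * sc$Co
  list(error = (closure_uptake - g$total_uptake) / g$total_uptake,
       grid = g,
       closure = c(sc, list(uptake = closure_uptake, k = k_mean,
                            A_wa = A_wa, A_ws = A_ws, L = g$L_bar)))
}

# k_wall entries seen by water faces (one per wall face)
.wall_cells <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- integer(0)
  for (cell in which(mask == ".")) {
    i <- (cell - 1) %% nr + 1; j <- (cell - 1) %/% nr + 1
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ii <- i + d[1]; jj <- j + d[2]
      if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      if (mask[ii, jj] == "W") out <- c(out, (jj - 1) * nr + ii)
    }
  }
  out
}
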