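#' Construct a distributed-multipole environment
#'
#' The environment is a tibble with one row per expansion site carrying a
#' position (Angstrom), a monopole charge q (e) and, optionally, a point
#' dipole (au), a traceless Cartesian quadrupole (au, Buckingham convention)
#' and an anisotropic dipole-dipole polarizability tensor (au). Missing
#' higher orders are stored as zeros. Quadrupoles are detraced on
#' construction (with a warning when |trace| > 1e-8); polarizability and
#' quadrupole tensors must be symmetric.
#'
#' @param x,y,z site positions (Angstrom).
#' @param q monopoles (e).
#' @param dipole `n x 3` matrix of dipoles (au), or `NULL`.
#' @param quadrupole `n x 6` matrix, columns `xx xy xz yy yz zz` (au), or `NULL`.
#' @param polarizability `n x 6` matrix, same column order (au), or `NULL`.
#' @param state state label, e.g. `"donor"` or `"acceptor"`.
#' @return A tibble of class `vibrolf_environment` with columns
#'   `x,y,z,q,dx,dy,dz,qxx,qxy,qxz,qyy,qyz,qzz,axx,axy,axz,ayy,ayz,azz`.
#' @export
multipole_environment <- function(x, y, z, q, dipole = NULL, quadrupole = NULL,
                                  polarizability = NULL, state = "donor") {
  n <- length(x)
  stopifnot(length(y) == n, length(z) == n, length(q) == n)
  zero3 <- matrix(0, n, 3)
  zero6 <- matrix(0, n, 6)
  dipole <- if (is.null(dipole)) zero3 else as.matrix(dipole)
  quadrupole <- if (is.null(quadrupole)) zero6 else as.matrix(quadrupole)
  polarizability <- if (is.null(polarizability)) zero6 else as.matrix(polarizability)
  stopifnot(all(dim(dipole) == c(n, 3)), all(dim(quadrupole) == c(n, 6)),
            all(dim(polarizability) == c(n, 6)))
  tr <- quadrupole[, 1] + quadrupole[, 4] + quadrupole[, 6]
  if (any(abs(tr) > 1e-8)) {
    warning("quadrupole trace removed (|trace| > 1e-8 au on ",
            sum(abs(tr) > 1e-8), " site(s))", call. = FALSE)
  }
  quadrupole[, c(1, 4, 6)] <- quadrupole[, c(1, 4, 6)] - tr / 3
  env <- tibble::tibble(
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    q = as.numeric(q),
    dx = dipole[, 1], dy = dipole[, 2], dz = dipole[, 3],
    qxx = quadrupole[, 1], qxy = quadrupole[, 2], qxz = quadrupole[, 3],
    qyy = quadrupole[, 4], qyz = quadrupole[, 5], qzz = quadrupole[, 6],
    axx = polarizability[, 1], axy = polarizability[, 2],
    axz = polarizability[, 3], ayy = polarizability[, 4],
    ayz = polarizability[, 5], azz = polarizability[, 6]
  )
  attr(env, "state") <- state
  class(env) <- c("vibrolf_environment", class(env))
  env
}

#' Read a distributed-multipole potential file
#'
#' One site per line:
#' `index x y z q [dx dy dz] [qxx qxy qxz qyy qyz qzz] [axx axy axz ayy ayz azz]`
#' with positions in Angstrom and moments/polarizabilities in atomic units.
#' Missing trailing groups default to zero. Lines starting with `#` are
#' comments.
#'
#' @param path file path.
#' @param state state label attached to the environment.
#' @return A [multipole_environment()].
#' @export
read_potential <- function(path, state = "donor") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop(path, ": no sites", call. = FALSE)
  parts <- strsplit(trimws(lines), "\\s+")
  len <- vapply(parts, length, 1L)
  ok_len <- c(5L, 8L, 14L, 20L)
  if (any(!len %in% ok_len)) {
    b <- which(!len %in% ok_len)[1]
    stop(sprintf("%s:%d: %d fields; expected 5, 8, 14 or 20",
                 path, lineno[b], len[b]), call. = FALSE)
  }
  num <- lapply(parts, function(p) suppressWarnings(as.numeric(p)))
  bad <- which(vapply(num, anyNA, TRUE))
  if (length(bad)) {
    stop(sprintf("%s:%d: non-numeric field", path, lineno[bad[1]]), call. = FALSE)
  }
  idx <- vapply(num, `[[`, 0, 1)
  if (anyDuplicated(idx)) {
    stop(sprintf("%s: duplicate site index %g", path, idx[anyDuplicated(idx)]),
         call. = FALSE)
  }
  pad <- function(v) c(v[-1], rep(0, 19 - (length(v) - 1)))
  m <- t(vapply(num, pad, numeric(19)))
  multipole_environment(
    x = m[, 1], y = m[, 2], z = m[, 3], q = m[, 4],
    dipole = m[, 5:7, drop = FALSE],
    quadrupole = m[, 8:13, drop = FALSE],
    polarizability = m[, 14:19, drop = FALSE],
    state = state
  )
}

#' Write a multipole environment to a potential file
#'
#' Inverse of [read_potential()]; trailing all-zero groups are kept so that
#' round trips are field-for-field identical.
#'
#' @param env a [multipole_environment()].
#' @param path output path.
#' @param digits numeric precision.
#' @return `path`, invisibly.
#' @export
write_potential <- function(env, path, digits = 12) {
  m <- as.matrix(env[, c("x", "y", "z", "q", "dx", "dy", "dz",
                         "qxx", "qxy", "qxz", "qyy", "qyz", "qzz",
                         "axx", "axy", "axz", "ayy", "ayz", "azz")])
  fmt <- paste(c("%d", rep(sprintf("%%.%dg", digits), 19)), collapse = " ")
  lines <- vapply(seq_len(nrow(m)), function(i) {
    do.call(sprintf, c(list(fmt, i), as.list(m[i, ])))
  }, "")
  writeLines(c("# index x y z q [dx dy dz] [qxx..qzz] [axx..azz]  (Angstrom, au)",
               lines), path)
  invisible(path)
}

# expand a packed 6-vector (xx xy xz yy yz zz) to a symmetric 3x3
.unpack_sym <- function(v) {
  matrix(c(v[1], v[2], v[3],
           v[2], v[4], v[5],
           v[3], v[5], v[6]), 3, 3)
}
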