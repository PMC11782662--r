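# internal numeric helpers shared across modules

# Evaluate expr with a locally seeded RNG, restoring global state afterwards.
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(expr)
}

vecNorm <- function(v) sqrt(sum(v^2))

normalize <- function(v) {
    n <- vecNorm(v)
    if (n < 1e-12) stop("cannot normalize a zero vector", call. = FALSE)
    v / n
}

# n random unit vectors (rows), consuming the current RNG stream
randomUnitVectors <- function(n) {
    m <- matrix(stats::rnorm(3 * n), ncol = 3)
    m / sqrt(rowSums(m^2))
}

# n points uniform in a sphere of given radius, consuming the RNG stream
uniformInSphere <- function(n, radius) {
    u <- randomUnitVectors(n)
    r <- radius * stats::runif(n)^(1 / 3)
    u * r
}

# Rotation matrix for a right-handed rotation by angle about a unit axis
rotationMatrix <- function(axis, angle) {
    u <- normalize(axis)
    c0 <- cos(angle); s0 <- sin(angle); v0 <- 1 - c0
    matrix(c(
        c0 + u[1]^2 * v0, u[1] * u[2] * v0 - u[3] * s0, u[1] * u[3] * v0 + u[2] * s0,
        u[2] * u[1] * v0 + u[3] * s0, c0 + u[2]^2 * v0, u[2] * u[3] * v0 - u[1] * s0,
        u[3] * u[1] * v0 - u[2] * s0, u[3] * u[2] * v0 + u[1] * s0, c0 + u[3]^2 * v0
    ), nrow = 3, byrow = TRUE)
}

# Tilt a unit vector by an angle drawn uniformly from (0, maxAngle] about a
# random perpendicular axis; consumes the RNG stream.
perturbDirection <- function(u, maxAngle) {
    ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    perp1 <- normalize(cross3(u, ref))
    phi <- stats::runif(1, 0, 2 * pi)
    axis <- cos(phi) * perp1 + sin(phi) * cross3(u, perp1)
    ang <- stats::runif(1, 0, maxAngle)
    as.numeric(rotationMatrix(axis, ang) %*% u)
}

cross3 <- function(a, b) {
    c(a[2] * b[3] - a[3] * b[2],
      a[3] * b[1] - a[1] * b[3],
      a[1] * b[2] - a[2] * b[1])
}

stopifnotScalarPositive <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
        stop(sprintf("'%s' must be a single positive finite number", name),
             call. = FALSE)
    invisible(x)
}
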