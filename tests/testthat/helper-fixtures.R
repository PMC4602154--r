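# Shared fixtures and independent oracles, built in code at test time.

# brute-force lattice enumeration of a ball mask (independent of make_sphere)
brute_sphere_count <- function(radius, dims) {
  ctr <- dims / 2
  n <- 0L
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) {
    dz <- (seq_len(dims[3]) - 0.5) - ctr[3]
    d2 <- (i - 0.5 - ctr[1])^2 + (j - 0.5 - ctr[2])^2 + dz^2
    n <- n + sum(d2 <= radius^2)
  }
  n
}

# brute-force 2-D disc lattice count centered at (n1/2, n2/2)
brute_disc_count <- function(radius, n1, n2) {
  xs <- seq_len(n1) - 0.5 - n1 / 2
  ys <- seq_len(n2) - 0.5 - n2 / 2
  sum(outer(xs^2, ys^2, `+`) <= radius^2)
}

# hand-built closed unit cube mesh (12 triangles, outward winding)
unit_cube_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
             c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  f <- rbind(c(1, 3, 2), c(1, 4, 3),    # z = 0, normal -z
             c(5, 6, 7), c(5, 7, 8),    # z = 1, normal +z
             c(1, 2, 6), c(1, 6, 5),    # y = 0
             c(2, 3, 7), c(2, 7, 6),    # x = 1
             c(3, 4, 8), c(3, 8, 7),    # y = 1
             c(4, 1, 5), c(4, 5, 8))    # x = 0
  triangle_mesh(v, f)
}

# parametric torus mesh: ring radius R, tube radius rho, nu x nv grid
torus_mesh <- function(R, rho, nu = 200, nv = 100) {
  us <- (seq_len(nu) - 1) / nu * 2 * pi   # around the ring
  vs <- (seq_len(nv) - 1) / nv * 2 * pi   # around the tube
  vid <- function(i, j) ((i - 1) %% nu) * nv + ((j - 1) %% nv) + 1
  verts <- matrix(0, nu * nv, 3)
  for (i in seq_len(nu)) {
    cu <- cos(us[i]); su <- sin(us[i])
    ring <- R + rho * cos(vs)
    verts[vid(i, seq_len(nv)), ] <- cbind(ring * cu, ring * su, rho * sin(vs))
  }
  f <- matrix(0L, 2 * nu * nv, 3)
  k <- 1L
  for (i in seq_len(nu)) for (j in seq_len(nv)) {
    a <- vid(i, j); b <- vid(i + 1, j); c <- vid(i + 1, j + 1); d <- vid(i, j + 1)
    f[k, ] <- c(a, b, c); f[k + 1L, ] <- c(a, c, d)
    k <- k + 2L
  }
  triangle_mesh(verts, f)
}

# standard smi phantom-validation parameters (analytic targets need the mesh
# relaxed close to the continuum; see the methods vignette)
phantom_smi_params <- list(resample_factor = 1, smoothing = 0.5,
                           smooth_iterations = 10)

smi_phantom <- function(img, boundary = "capped")
  do.call(compute_smi, c(list(img = img, boundary = boundary),
                         phantom_smi_params))
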