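# Shared in-code fixtures. Heavier phantoms are built once per test run and
# cached in this environment.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(build)
  .fixtures[[name]]
}

# Label map of a centred digital ball: radius mm, optional shells.
ball_map <- function(radius, spacing = 1, t_cortex = 0, t_csf = 0,
                     margin = 3) {
  ext <- 2 * (radius + t_cortex + t_csf + margin)
  n <- as.integer(ceiling(ext / spacing))
  ctr <- n * spacing / 2
  x <- (seq_len(n) - 0.5) * spacing - ctr
  r <- sqrt(outer(outer(x^2, x^2, "+"), x^2, "+"))
  lab <- array(0L, rep(n, 3))
  lab[r <= radius] <- 1L
  if (t_cortex > 0) lab[r > radius & r <= radius + t_cortex] <- 2L
  if (t_csf > 0) lab[r > radius + t_cortex & r <= radius + t_cortex + t_csf] <- 3L
  tissue_label_map(lab, spacing = rep(spacing, 3))
}

# Axis-aligned slab: UWM below z0, CoGM of thickness d above it, CSF above.
slab_map <- function(d = 3, spacing = 0.25, nxy = 28L, pad = 2) {
  nz <- as.integer(ceiling((d + 2 * pad) / spacing))
  lab <- array(0L, c(nxy, nxy, nz))
  z <- (seq_len(nz) - 0.5) * spacing
  for (k in seq_len(nz))
    lab[, , k] <- if (z[k] < pad) 1L else if (z[k] < pad + d) 2L else 3L
  tissue_label_map(lab, spacing = rep(spacing, 3))
}

small_shell <- function() fixture("small_shell", {
  ball_map(10, spacing = 0.5, t_cortex = 3, t_csf = 2)
})

small_folded <- function(a = 0.2) {
  fixture(paste0("folded_", a), {
    generate_phantom(phantom_spec(R0 = 16, fold_amp = a, fold_freq = c(6, 6),
                                  t_cortex = 2, t_csf = 2, spacing = 0.8),
                     truth = "none")
  })
}
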