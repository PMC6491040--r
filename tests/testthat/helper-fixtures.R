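# shared fixtures, built in code at test time

# a calibrated oddity link at moderate Monte-Carlo size, computed once
cached_link <- local({
  lk <- NULL
  function() {
    if (is.null(lk)) lk <<- calibrate_link(n_triads = 2e4, seed = 1)
    lk
  }
})

# minimal identity-feature backend: one channel, the raw pixels.
# strictly local and exactly rotation-equivariant, for locality and
# permutation probes of the pooling machinery.
identity_backend <- function() {
  structure(list(
    input_sizes = NA, layer_channels = 1L, n_channels = 1L,
    forward = function(x) list(features = array(x, c(dim(x), 1L)),
                               pos = array(TRUE, c(dim(x), 1L))),
    vjp = function(gbar, pos) gbar[, , 1],
    differentiable = TRUE), class = "feature_backend")
}

# exact 90-degree ccw rotation about the pixel-center of a square raster
rot90_raster <- function(m) {
  side <- nrow(m)
  out <- m                      # preserves storage mode

  for (i in seq_len(side)) out[, side + 1 - i] <- m[i, ]
  out
}

# pixel eccentricity map under the package's coordinate convention
ecc_map <- function(side) {
  ctr <- (side - 1) / 2
  xs <- seq_len(side) - 1
  sqrt(outer((xs - ctr)^2, (xs - ctr)^2, "+"))
}

# small raw-trial table builder
make_raw <- function(n, no_resp = 0, fix_break = 0) {
  d <- data.frame(
    participant = rep("p1", n), image = rep("i1", n),
    image_type = rep("scene", n), comparison = rep("orig_vs_synth", n),
    model = rep("FS", n), scale = rep(0.5, n), response = rep(1L, n),
    correct = rep(c(TRUE, FALSE), length.out = n),
    fixation_break = rep(FALSE, n))
  if (no_resp > 0) d$response[seq_len(no_resp)] <- NA
  if (fix_break > 0) d$fixation_break[no_resp + seq_len(fix_break)] <- TRUE
  d
}
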