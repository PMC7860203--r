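# Fixture builders shared across the suite. Everything is generated in
# code; no stored data files.

# Binary disk mask of radius r_px pixels on an n x n grid.
make_disk_mask <- function(n, r_px) {
  cx <- (n + 1) / 2
  ij <- expand.grid(i = seq_len(n), j = seq_len(n))
  matrix(as.numeric((ij$i - cx)^2 + (ij$j - cx)^2 <= r_px^2), n, n)
}

# Coordinate matrices for an n x n grid spanning [-half, half] in both
# directions (rows = y, columns = x), plus the spacing.
make_grid <- function(n, half = 1) {
  xs <- seq(-half, half, length.out = n)
  list(X = matrix(xs, n, n, byrow = TRUE), Y = matrix(xs, n, n),
       h = xs[2L] - xs[1L])
}

# Solid-body rotation plane: u = -omega*y, v = omega*x, circular mask.
make_rotation_plane <- function(n, omega, mask_radius = 0.9) {
  g <- make_grid(n)
  mask <- g$X^2 + g$Y^2 <= mask_radius^2
  velocity_plane(u = -omega * g$Y, v = omega * g$X, spacing = g$h, mask = mask)
}

# A laminar-only tree (no bends): the network is a linear resistor
# circuit, so split and drop have electrical closed forms.
make_linear_tree <- function(d_left = 6, d_right = 6) {
  venous_tree(list(
    vessel_segment("SSS", 107.8, 5.49),
    vessel_segment("StS", 42.9, 5.0),
    vessel_segment("TS-L", 50, d_left),
    vessel_segment("PSS-L", 40, d_left),
    vessel_segment("DSS-L", 40, d_left),
    vessel_segment("IJV-L", 30, d_left),
    vessel_segment("TS-R", 50, d_right),
    vessel_segment("PSS-R", 40, d_right),
    vessel_segment("DSS-R", 40, d_right),
    vessel_segment("IJV-R", 30, d_right)))
}

# Series Poiseuille resistance of one branch of a linear tree, SI units.
branch_resistance <- function(tree, names, mu = 0.0035) {
  sum(vapply(names, function(nm) {
    s <- tree$segments[[nm]]
    poiseuille_resistance(s$length, s$diameter, mu)
  }, 0))
}
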