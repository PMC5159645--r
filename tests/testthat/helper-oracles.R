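# Independent oracles, kept deliberately separate from the implementation.

# Exposed area of one of two equal overlapping spheres of radius R at
# centre distance d: full sphere minus the occluded spherical cap.
two_sphere_exposed <- function(R, d) {
  if (d >= 2 * R) return(4 * pi * R^2)
  4 * pi * R^2 - 2 * pi * R * (R - d / 2)
}

# Product-moment correlation written out longhand.
pearson_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Minimal PDB writer for tiny synthetic chains (text fixture generator).
write_mini_pdb <- function(atoms, path, chain = "A") {
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    sprintf("ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            i, atoms$atom_name[i], atoms$residue_base[i], chain,
            atoms$residue_index[i] + 1L,
            atoms$x[i], atoms$y[i], atoms$z[i], atoms$element[i])
  }, character(1))
  writeLines(c(lines, "END"), path)
}
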