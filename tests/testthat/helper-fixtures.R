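# Text-format fixture writers and brute-force oracles shared across tests.

write_xvg <- function(rows, path = tempfile(fileext = ".xvg"),
                      header = c("# synthetic pull force",
                                 "@ title \"pull\"")) {
  writeLines(c(header, rows), path)
  path
}

# Minimal fixed-column PDB ATOM record (coordinates in Angstrom).
pdb_atom_line <- function(serial, name, resname, chain, resid, x, y, z,
                          element = substr(name, 1, 1), record = "ATOM") {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, " ", resname, chain, resid, " ",
          x, y, z, 1.00, 0.00, element)
}

write_pdb <- function(atom_lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(atom_lines, "END"), path)
  path
}

write_gro <- function(df, path = tempfile(fileext = ".gro"),
                      box = "  10.00000  10.00000  10.00000") {
  lines <- c("synthetic", sprintf("%5d", nrow(df)))
  for (i in seq_len(nrow(df))) {
    lines <- c(lines, sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                              df$resid[i], df$resname[i], df$name[i], i,
                              df$x[i], df$y[i], df$z[i]))
  }
  writeLines(c(lines, box), path)
  path
}

# Structure model straight from an atom table (bypasses file formats).
toy_model <- function(chain, resid, x, y = 0, z = 0, name = "CA",
                      element = "C", frame = 0L) {
  n <- max(length(chain), length(resid), length(x))
  structure_model(data.frame(
    name = rep_len(name, n), element = rep_len(element, n),
    resid = rep_len(as.integer(resid), n),
    resname = "GLY", chain = rep_len(chain, n),
    x = rep_len(x, n), y = rep_len(y, n), z = rep_len(z, n),
    stringsAsFactors = FALSE), frame = frame)
}

# Exhaustive pairwise AUC oracle: fraction of (positive, negative) pairs
# ranked correctly, ties counted one half.
auc_pairwise <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# Analytic exposed area of two identical intersecting spheres of extended
# radius R at centre distance d (each loses a cap of height R - d/2).
two_sphere_union_area <- function(R, d) {
  if (d >= 2 * R) return(2 * 4 * pi * R^2)
  2 * 2 * pi * R * (R + d / 2)
}

# Elongation at which a planted logistic contact-area decay crosses a
# threshold: eq_mean * plogis(-(x - center)/width) == thr.
logistic_crossing <- function(eq_mean, center, width, thr) {
  center + width * log(eq_mean / thr - 1)
}
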