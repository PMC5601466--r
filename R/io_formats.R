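# Readers and writers for the on-disk formats the pipeline touches:
# GROMACS pull-force XVG, PDB/GRO coordinates, TSV tables.

#' Construct a two-channel pull-force trace
#'
#' Container for the pulling forces recorded at the two termini of a
#' force-probe MD simulation. Forces at the two moving springs have opposite
#' signs; the analysis combines them as F = (f1 - f2)/2.
#'
#' @param time sample times in ns, strictly increasing (nominal spacing
#'   0.05 ns).
#' @param f1,f2 per-sample forces in pN at either pulled terminus.
#' @param v_pull pulling velocity in nm/ns (> 0); the net rate at which the
#'   two springs separate.
#' @param k_spring spring force constant in pN/nm (> 0).
#' @param label free-text identifier (system, replica).
#' @return An object of class `force_trace`.
#' @export
force_trace <- function(time, f1, f2, v_pull, k_spring, label = "") {
  time <- as.numeric(time); f1 <- as.numeric(f1); f2 <- as.numeric(f2)
  if (length(time) == 0L) stop("empty force trace")
  if (length(f1) != length(time) || length(f2) != length(time))
    stop("f1 and f2 must have the same length as time")
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (!is.numeric(v_pull) || v_pull <= 0) stop("v_pull must be > 0")
  if (!is.numeric(k_spring) || k_spring <= 0) stop("k_spring must be > 0")
  structure(
    list(time = time, f1 = f1, f2 = f2,
         v_pull = v_pull, k_spring = k_spring, label = label),
    class = "force_trace"
  )
}

#' @export
print.force_trace <- function(x, ...) {
  cat(sprintf(
    "force_trace '%s': %d samples, t = [%g, %g] ns, v_pull = %g nm/ns, k = %g pN/nm\n",
    x$label, length(x$time), x$time[1], x$time[length(x$time)],
    x$v_pull, x$k_spring))
  invisible(x)
}

#' Read a GROMACS-style pull-force XVG file
#'
#' Lines beginning with `#` or `@` are metadata and may appear anywhere.
#' Data lines hold 2 or 3 whitespace-separated numbers: time (ps) and one
#' or two force channels. Two-column files describe a single spring; the
#' second channel is synthesised as the negative of the first, so the
#' combined force (f1 - f2)/2 reduces to the single channel.
#'
#' @param path file path.
#' @param v_pull,k_spring pulling velocity (nm/ns) and spring constant
#'   (pN/nm) attached as metadata.
#' @param unit_mode `"gmx"`: forces in kJ/(mol nm), converted to pN by
#'   1.6605390; `"pN"`: forces passed through.
#' @param label trace label.
#' @return A [force_trace]; time is converted ps to ns.
#' @export
read_force_xvg <- function(path, v_pull, k_spring,
                           unit_mode = c("gmx", "pN"), label = basename(path)) {
  unit_mode <- match.arg(unit_mode)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_meta <- grepl("^\\s*[#@]", lines) | !nzchar(trimws(lines))
  data_idx <- which(!is_meta)
  if (length(data_idx) == 0L) stop("empty trace: no data lines in ", path)
  rows <- lapply(data_idx, function(i) {
    fields <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals) || !(length(vals) %in% c(2L, 3L)))
      stop(sprintf("malformed numeric line %d in %s: '%s'", i, path, lines[i]))
    vals
  })
  ncols <- unique(vapply(rows, length, integer(1)))
  if (length(ncols) != 1L)
    stop("inconsistent column count in ", path)
  m <- do.call(rbind, rows)
  time_ns <- m[, 1] / 1000  # ps -> ns
  if (any(diff(time_ns) <= 0)) stop("non-monotone time in ", path)
  conv <- if (unit_mode == "gmx") mech_constants$kj_mol_nm_to_pn else 1
  f1 <- m[, 2] * conv
  f2 <- if (ncols == 3L) m[, 3] * conv else -f1
  force_trace(time_ns, f1, f2, v_pull, k_spring, label = label)
}

#' Construct a structure model
#'
#' Flat atom table for one frame: names, elements, residue bookkeeping and
#' coordinates in nm.
#'
#' @param atoms data.frame with columns `name`, `element`, `resid`,
#'   `resname`, `chain`, `x`, `y`, `z` (nm).
#' @param frame integer frame id.
#' @return Object of class `structure_model`.
#' @export
structure_model <- function(atoms, frame = 0L) {
  req <- c("name", "element", "resid", "resname", "chain", "x", "y", "z")
  if (!all(req %in% names(atoms)))
    stop("atoms must have columns: ", paste(req, collapse = ", "))
  if (nrow(atoms) > 0 && !all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates")
  structure(list(atoms = atoms, frame = as.integer(frame)),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model: frame %d, %d atoms, %d residues\n",
              x$frame, nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resid)))))
  invisible(x)
}

# Element inference from a PDB/GRO atom name: first alphabetic character
# after stripping leading digits, with two-letter cases for common ions.
infer_element <- function(name) {
  nm <- toupper(gsub("^[0-9 ']+", "", trimws(name)))
  two <- substr(nm, 1, 2)
  ifelse(two %in% c("CL", "MG", "ZN", "FE", "BR"), two,
         substr(nm, 1, 1))
}

parse_pdb <- function(lines, frame = 0L) {
  rec <- substr(lines, 1, 6)
  atom_lines <- lines[rec == "ATOM  " | rec == "HETATM"]
  if (length(atom_lines) == 0L)
    return(structure_model(empty_atoms(), frame))
  # PDB 3.3 fixed columns
  name    <- trimws(substr(atom_lines, 13, 16))
  resname <- trimws(substr(atom_lines, 18, 20))
  chain   <- substr(atom_lines, 22, 22)
  resid   <- as.integer(trimws(substr(atom_lines, 23, 26)))
  x <- as.numeric(substr(atom_lines, 31, 38)) / 10  # Angstrom -> nm
  y <- as.numeric(substr(atom_lines, 39, 46)) / 10
  z <- as.numeric(substr(atom_lines, 47, 54)) / 10
  elem_col <- trimws(substr(atom_lines, 77, 78))
  element <- ifelse(nzchar(elem_col), toupper(elem_col), infer_element(name))
  if (anyNA(x) || anyNA(y) || anyNA(z) || anyNA(resid))
    stop("unparseable ATOM record in PDB input")
  het <- substr(atom_lines, 1, 6) == "HETATM"
  if (all(het)) warning("structure contains HETATM records only")
  structure_model(data.frame(
    name = name, element = element, resid = resid, resname = resname,
    chain = chain, x = x, y = y, z = z, stringsAsFactors = FALSE), frame)
}

parse_gro <- function(lines, frame = 0L) {
  if (length(lines) < 3L) stop("truncated GRO file")
  natoms <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(natoms)) stop("unparseable atom count in GRO file")
  if (length(lines) < 2L + natoms) stop("GRO file shorter than declared atom count")
  al <- lines[3:(2 + natoms)]
  # GROMACS fixed columns: resid(5) resname(5) name(5) serial(5) x y z (%8.3f)
  resid   <- as.integer(trimws(substr(al, 1, 5)))
  resname <- trimws(substr(al, 6, 10))
  name    <- trimws(substr(al, 11, 15))
  x <- as.numeric(substr(al, 21, 28))
  y <- as.numeric(substr(al, 29, 36))
  z <- as.numeric(substr(al, 37, 44))
  if (anyNA(x) || anyNA(y) || anyNA(z) || anyNA(resid))
    stop("unparseable coordinate record in GRO input")
  structure_model(data.frame(
    name = name, element = infer_element(name), resid = resid,
    resname = resname, chain = "A", x = x, y = y, z = z,
    stringsAsFactors = FALSE), frame)
}

empty_atoms <- function() {
  data.frame(name = character(), element = character(), resid = integer(),
             resname = character(), chain = character(),
             x = numeric(), y = numeric(), z = numeric(),
             stringsAsFactors = FALSE)
}

#' Read a structure file (PDB or GRO)
#'
#' Format is detected from the extension. PDB coordinates (Angstrom) are
#' converted to nm; GRO coordinates are already nm. When the PDB element
#' column is blank the element is inferred from the atom name.
#'
#' @param path file path ending in `.pdb` or `.gro`.
#' @return A [structure_model] (the first MODEL for multi-model PDBs).
#' @seealso [read_trajectory] for multi-frame input.
#' @export
read_structure <- function(path) {
  frames <- read_structure_frames(path)
  frames[[1]]
}

read_structure_frames <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path, warn = FALSE)
  if (ext == "gro") return(list(parse_gro(lines)))
  if (ext != "pdb") stop("unknown structure extension: .", ext)
  model_starts <- which(substr(lines, 1, 5) == "MODEL")
  if (length(model_starts) <= 1L) return(list(parse_pdb(lines)))
  model_ends <- which(substr(lines, 1, 6) == "ENDMDL")
  if (length(model_ends) != length(model_starts))
    stop("unbalanced MODEL/ENDMDL records")
  lapply(seq_along(model_starts), function(i)
    parse_pdb(lines[model_starts[i]:model_ends[i]], frame = i - 1L))
}

#' Read an ordered set of structure files as a trajectory
#'
#' @param paths ordered character vector of PDB/GRO paths; a single
#'   multi-MODEL PDB yields one frame per MODEL.
#' @return List of [structure_model] with frame ids `0..n-1`.
#' @export
read_trajectory <- function(paths) {
  frames <- unlist(lapply(paths, read_structure_frames), recursive = FALSE)
  counts <- vapply(frames, function(f) nrow(f$atoms), integer(1))
  if (length(unique(counts)) > 1L)
    stop("atom-count mismatch between frames: ",
         paste(unique(counts), collapse = ", "))
  for (i in seq_along(frames)) frames[[i]]$frame <- i - 1L
  frames
}

#' Write a table as TSV with header
#'
#' Values round-trip through [read_tsv()] to 6 significant digits.
#'
#' @param table data.frame.
#' @param path output path.
#' @param allow_empty write a header-only file for an empty table instead of
#'   erroring.
#' @export
write_tsv <- function(table, path, allow_empty = FALSE) {
  stopifnot(is.data.frame(table))
  if (nrow(table) == 0L && !allow_empty)
    stop("refusing to write empty table (set allow_empty = TRUE)")
  out <- table
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) signif(v, 10))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV table written by [write_tsv()]
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
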