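# Monoisotopic-free average residue masses (Da) of the 20 standard amino
# acids (residue = amino acid minus water).  Unknown residues fall back to
# the mean of this table.
RESIDUE_MASS <- c(
  ALA =  71.0788, ARG = 156.1875, ASN = 114.1038, ASP = 115.0886,
  CYS = 103.1388, GLN = 128.1307, GLU = 129.1155, GLY =  57.0519,
  HIS = 137.1411, ILE = 113.1594, LEU = 113.1594, LYS = 128.1741,
  MET = 131.1926, PHE = 147.1766, PRO =  97.1167, SER =  87.0782,
  THR = 101.1051, TRP = 186.2132, TYR = 163.1760, VAL =  99.1326)

#' Construct a weighted point cloud
#'
#' @param coords `N x 3` numeric matrix of positions in Angstrom.
#' @param weights `N` positive weights (default all 1).
#' @param source_label free-text provenance string.
#' @return object of class `point_cloud`.
#' @export
point_cloud <- function(coords, weights = rep(1, nrow(coords)),
                        source_label = "") {
  coords <- as.matrix(coords)
  if (nrow(coords) < 1L || ncol(coords) != 3L || any(!is.finite(coords))) {
    abort_validation("coords must be a finite N x 3 matrix with N >= 1")
  }
  weights <- as.numeric(weights)
  if (length(weights) != nrow(coords) || any(!is.finite(weights)) ||
      any(weights <= 0)) {
    abort_validation("weights must be positive, finite, one per point")
  }
  dimnames(coords) <- NULL
  structure(list(coords = coords, weights = weights,
                 source_label = as.character(source_label)[1L]),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("point_cloud: %d points, total weight %.6g [%s]\n",
              nrow(x$coords), sum(x$weights), x$source_label))
  invisible(x)
}

sniff_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("cif", "mmcif")) return("cif")
  if (ext %in% c("pdb", "ent")) return("pdb")
  head <- tryCatch(readLines(path, n = 50L, warn = FALSE),
                   error = function(e) character(0))
  if (any(grepl("^(_atom_site\\.|loop_|data_)", head))) return("cif")
  "pdb"
}

#' Read C-alpha coordinates from a PDB or mmCIF file
#'
#' Extracts one point per C-alpha atom of standard ATOM records, keeping
#' only blank or 'A' alternate locations so the cloud represents a single
#' conformer.  Hydrogens, waters and ligands (HETATM) are excluded; the
#' shape model is C-alpha based.  Non-standard residues that carry a CA
#' atom are kept.  The file format is sniffed from the extension and, when
#' ambiguous, from the content.
#'
#' @param path PDB or mmCIF file.
#' @param chain_filter optional chain identifier; only that chain is read.
#' @param weight_mode `"uniform"` (every point weighs 1) or
#'   `"residue_mass"` (standard average residue mass, mean mass for
#'   unknown residue types).
#' @return a [point_cloud()] in file order.
#' @export
read_point_cloud <- function(path, chain_filter = NULL,
                             weight_mode = c("uniform", "residue_mass")) {
  weight_mode <- match.arg(weight_mode)
  if (!file.exists(path)) {
    abort_io(sprintf("file '%s' does not exist", path))
  }
  fmt <- sniff_format(path)
  parsed <- tryCatch(
    suppressWarnings(
      if (fmt == "cif") bio3d::read.cif(path) else bio3d::read.pdb(path)),
    error = function(e) NULL)
  if (is.null(parsed) || is.null(parsed$atom) || nrow(parsed$atom) == 0L) {
    abort_io(sprintf("cannot parse '%s' as %s", path, toupper(fmt)))
  }
  at <- parsed$atom
  sel <- at$elety == "CA" & at$type == "ATOM" &
    (is.na(at$alt) | at$alt %in% c("", "A"))
  if (!is.null(chain_filter)) {
    sel <- sel & !is.na(at$chain) & at$chain %in% chain_filter
    if (!any(sel)) {
      abort_validation(sprintf(
        "chain filter '%s' matches no C-alpha atoms in '%s'",
        paste(chain_filter, collapse = ","), path))
    }
  }
  if (!any(sel)) {
    abort_validation(sprintf("no C-alpha atoms found in '%s'", path))
  }
  at <- at[sel, , drop = FALSE]
  w <- if (weight_mode == "uniform") {
    rep(1, nrow(at))
  } else {
    m <- RESIDUE_MASS[at$resid]
    m[is.na(m)] <- mean(RESIDUE_MASS)
    unname(m)
  }
  point_cloud(cbind(at$x, at$y, at$z), w,
              source_label = sprintf("%s:%s", basename(path),
                                     if (is.null(chain_filter)) "*"
                                     else paste(chain_filter, collapse = ",")))
}

#' Write a point cloud as a minimal PDB file
#'
#' One CA-only ATOM record per point (residue ALA, chain A), so synthetic
#' fixtures can exercise the file-reading path end-to-end.
#'
#' @param cloud a `point_cloud`.
#' @param path output path.
#' @export
write_point_cloud_pdb <- function(cloud, path) {
  n <- nrow(cloud$coords)
  lines <- sprintf(
    "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(n) %% 100000L, seq_len(n) %% 10000L,
    cloud$coords[, 1], cloud$coords[, 2], cloud$coords[, 3])
  ok <- tryCatch({ writeLines(c(lines, "END"), path); TRUE },
                 error = function(e) FALSE)
  if (!ok) abort_io(sprintf("cannot write PDB to '%s'", path))
  invisible(NULL)
}

#' Write a superposition result to JSON
#'
#' The document holds the 16 entries of the homogeneous transform in
#' row-major order, the dot-product score, the chosen candidate pair and
#' provenance labels.  Numbers are written at full precision, so
#' [read_transform()] reproduces the matrix bit-exactly.
#'
#' @param result a `superposition_result` (see [superpose()]).
#' @param path output JSON path.
#' @export
write_transform <- function(result, path) {
  if (!inherits(result, "superposition_result")) {
    abort_validation("write_transform expects a superposition_result")
  }
  tr <- result$transform
  if (!is.matrix(tr) || any(dim(tr) != c(4L, 4L)) || any(!is.finite(tr))) {
    abort_validation("transform must be a finite 4 x 4 matrix")
  }
  # numbers are formatted with 17 significant digits, which round-trips
  # IEEE doubles exactly; jsonlite's writer would stop at ~15
  num <- function(x) sprintf("%.17g", x)
  doc <- paste0(
    "{\n",
    '  "matrix": [', paste(num(as.vector(t(tr))), collapse = ", "), "],\n",
    '  "score": ', num(result$score), ",\n",
    '  "best_pair": [', paste(result$best_pair, collapse = ", "), "],\n",
    '  "moving": ', jsonlite::toJSON(as.character(result$moving)[1],
                                     auto_unbox = TRUE), ",\n",
    '  "fixed": ', jsonlite::toJSON(as.character(result$fixed)[1],
                                    auto_unbox = TRUE), "\n}\n")
  ok <- tryCatch({ writeLines(doc, path, sep = ""); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) abort_io(sprintf("cannot write transform to '%s'", path))
  invisible(NULL)
}

#' @rdname write_transform
#' @return `read_transform` returns the `superposition_result` restored
#'   from the file.
#' @export
read_transform <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file '%s' does not exist", path))
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) NULL)
  if (is.null(doc) || is.null(doc$matrix) || length(doc$matrix) != 16L) {
    abort_io(sprintf("'%s' is not a transform document", path))
  }
  structure(list(transform = matrix(as.numeric(doc$matrix), 4L, 4L,
                                    byrow = TRUE),
                 score = as.numeric(doc$score),
                 best_pair = as.integer(doc$best_pair),
                 moving = doc$moving, fixed = doc$fixed),
            class = "superposition_result")
}
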