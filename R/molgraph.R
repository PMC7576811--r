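#' Construct a hydrogen-suppressed molecular graph
#'
#' The substrate for the flexibility descriptors: heavy atoms as vertices,
#' covalent bonds as edges. Ring membership (an edge is in a ring iff it
#' lies on some cycle, i.e. is not a bridge), hybridization (any double or
#' aromatic bond makes an atom sp2, any triple bond sp, otherwise sp3) and
#' amide bonds (single C-N bond where that carbon bears a double-bonded
#' oxygen) are derived automatically.
#'
#' @param elements character vector of element symbols (heavy atoms only;
#'   C, H-free graph — explicit hydrogens are not allowed here).
#' @param bonds data frame or matrix with columns `i`, `j` (1-based atom
#'   indices) and `order` (1, 2, 3, or 4 for aromatic, the Molfile
#'   convention).
#' @param name optional compound name.
#' @return Object of class `eims_molgraph`: list with `atoms` (data frame:
#'   `element`, `hybridization`, `in_ring`, `degree`), `bonds` (data frame:
#'   `i`, `j`, `order`, `in_ring`, `amide`) and `name`.
#' @examples
#' # n-butane
#' g <- molecule_graph(rep("C", 4), cbind(i = 1:3, j = 2:4, order = 1))
#' rotatable_bond_count(g)  # 1
#' @export
molecule_graph <- function(elements, bonds, name = NULL) {
  elements <- toupper(as.character(elements))
  if (any(elements == "H"))
    stop("graph must be hydrogen-suppressed (no explicit H atoms)",
         call. = FALSE)
  n <- length(elements)
  if (n < 1L) stop("graph must contain at least one atom", call. = FALSE)
  bonds <- as.data.frame(bonds)
  if (nrow(bonds) > 0) {
    names(bonds)[1:3] <- c("i", "j", "order")
    bonds$i <- as.integer(bonds$i)
    bonds$j <- as.integer(bonds$j)
    bonds$order <- as.integer(bonds$order)
    if (any(bonds$i < 1 | bonds$i > n | bonds$j < 1 | bonds$j > n |
            bonds$i == bonds$j))
      stop("invalid bond indices", call. = FALSE)
    if (!all(bonds$order %in% 1:4))
      stop("bond order must be 1, 2, 3 or 4 (aromatic)", call. = FALSE)
  } else {
    bonds <- data.frame(i = integer(), j = integer(), order = integer())
  }

  ig <- igraph::graph_from_edgelist(
    cbind(bonds$i, bonds$j)[seq_len(nrow(bonds)), , drop = FALSE],
    directed = FALSE)
  if (igraph::vcount(ig) < n)
    ig <- igraph::add_vertices(ig, n - igraph::vcount(ig))
  if (n > 1L && !igraph::is_connected(ig))
    stop("heavy-atom graph is disconnected", call. = FALSE)

  deg <- igraph::degree(ig)
  # ring perception: an edge lies on a cycle iff it is not a bridge
  bridge_ids <- igraph::bridges(ig)
  bond_in_ring <- !(seq_len(nrow(bonds)) %in% as.integer(bridge_ids))
  atom_in_ring <- rep(FALSE, n)
  if (any(bond_in_ring)) {
    ring_atoms <- unique(c(bonds$i[bond_in_ring], bonds$j[bond_in_ring]))
    atom_in_ring[ring_atoms] <- TRUE
  }

  hyb <- rep("sp3", n)
  for (k in seq_len(nrow(bonds))) {
    o <- bonds$order[k]
    idx <- c(bonds$i[k], bonds$j[k])
    if (o == 2L || o == 4L) hyb[idx][hyb[idx] == "sp3"] <- "sp2"
    if (o == 3L) hyb[idx] <- "sp"
  }

  # amide: single C-N bond whose carbon carries a double-bonded O
  has_carbonyl <- rep(FALSE, n)
  for (k in seq_len(nrow(bonds))) {
    if (bonds$order[k] == 2L) {
      i <- bonds$i[k]; j <- bonds$j[k]
      if (elements[i] == "C" && elements[j] == "O") has_carbonyl[i] <- TRUE
      if (elements[j] == "C" && elements[i] == "O") has_carbonyl[j] <- TRUE
    }
  }
  amide <- vapply(seq_len(nrow(bonds)), function(k) {
    if (bonds$order[k] != 1L) return(FALSE)
    i <- bonds$i[k]; j <- bonds$j[k]
    (elements[i] == "C" && elements[j] == "N" && has_carbonyl[i]) ||
      (elements[j] == "C" && elements[i] == "N" && has_carbonyl[j])
  }, logical(1))

  structure(list(
    atoms = data.frame(element = elements, hybridization = hyb,
                       in_ring = atom_in_ring, degree = as.integer(deg),
                       stringsAsFactors = FALSE),
    bonds = cbind(bonds,
                  data.frame(in_ring = bond_in_ring, amide = amide)),
    name = name
  ), class = "eims_molgraph")
}

#' @export
print.eims_molgraph <- function(x, ...) {
  cat("Molecular graph", if (!is.null(x$name)) paste0("'", x$name, "'"),
      "\n  atoms:", nrow(x$atoms), " bonds:", nrow(x$bonds),
      " ring bonds:", sum(x$bonds$in_ring),
      " amide bonds:", sum(x$bonds$amide), "\n")
  invisible(x)
}

#' Parse an MDL Molfile (V2000) into a molecular graph
#'
#' Reads the counts line, atom block and bond block of a V2000 connection
#' table, strips explicit hydrogens, and builds a [molecule_graph()] with
#' derived ring, hybridization and amide annotations.
#'
#' @param text character vector of file lines or a single string.
#' @return An `eims_molgraph` object; line 1 of the header becomes `name`.
#' @export
parse_molfile <- function(text) {
  lines <- .as_lines(text)
  if (length(lines) < 4L)
    stop("Molfile format error: fewer than 4 header lines", call. = FALSE)
  counts <- lines[4L]
  natoms <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
  if (is.na(natoms) || is.na(nbonds) || natoms < 1L ||
      !grepl("V2000", counts))
    stop("Molfile format error: malformed V2000 counts line", call. = FALSE)
  if (length(lines) < 4L + natoms + nbonds)
    stop("Molfile format error: truncated atom/bond block", call. = FALSE)

  atom_lines <- lines[5:(4L + natoms)]
  elements <- trimws(substr(atom_lines, 32L, 34L))
  if (any(!nzchar(elements)))
    stop("Molfile format error: missing element symbol", call. = FALSE)

  if (nbonds > 0L) {
    bond_lines <- lines[(5L + natoms):(4L + natoms + nbonds)]
    bi <- as.integer(substr(bond_lines, 1L, 3L))
    bj <- as.integer(substr(bond_lines, 4L, 6L))
    bo <- as.integer(substr(bond_lines, 7L, 9L))
    if (any(is.na(bi)) || any(is.na(bj)) || any(is.na(bo)))
      stop("Molfile format error: malformed bond line", call. = FALSE)
  } else {
    bi <- bj <- bo <- integer()
  }

  keep <- toupper(elements) != "H"
  idx_map <- cumsum(keep)
  heavy_bond <- keep[bi] & keep[bj]
  molecule_graph(elements[keep],
                 data.frame(i = idx_map[bi[heavy_bond]],
                            j = idx_map[bj[heavy_bond]],
                            order = bo[heavy_bond]),
                 name = trimws(lines[1L]))
}

#' @rdname parse_molfile
#' @param path path to a `.mol` file.
#' @export
read_molfile <- function(path) parse_molfile(readLines(path, warn = FALSE))
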