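# Multi-chain, multi-frame coordinate ensembles.
#
# A `molecular_system` is a list with
#   atoms : data.frame(eleno, elety, resid, chain, resno, elesy)
#           (atom name `elety`, residue name `resid`, element `elesy`,
#            1-based residue numbering per chain, coordinates in angstrom)
#   xyz   : numeric array [n_atoms, 3, n_frames]
#   box   : NULL or orthorhombic box lengths (angstrom triple)
# All frames share the atom roster.

#' Construct a molecular system
#'
#' @param atoms data.frame with columns `elety` (atom name), `resid`
#'   (residue name), `chain`, `resno` (1-based residue number); optional
#'   `eleno`, `elesy` (element, guessed from the atom name if absent).
#' @param xyz coordinates: `n_atoms x 3` matrix (single frame) or
#'   `n_atoms x 3 x n_frames` array, angstrom.
#' @param box optional orthorhombic box lengths, numeric triple
#'   (angstrom); enables minimum-image distances.
#' @return object of class `molecular_system`.
#' @export
molecular_system <- function(atoms, xyz, box = NULL) {
  need <- c("elety", "resid", "chain", "resno")
  if (!all(need %in% names(atoms)))
    stop("atoms needs columns: ", paste(need, collapse = ", "))
  if (is.matrix(xyz)) xyz <- array(xyz, dim = c(nrow(xyz), 3, 1))
  stopifnot(length(dim(xyz)) == 3, dim(xyz)[2] == 3,
            dim(xyz)[1] == nrow(atoms))
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  if (!is.null(box)) {
    box <- as.numeric(box)
    stopifnot(length(box) == 3, all(box > 0))
  }
  if (is.null(atoms$eleno)) atoms$eleno <- seq_len(nrow(atoms))
  if (is.null(atoms$elesy)) atoms$elesy <- .guess_element(atoms$elety)
  atoms$chain <- as.character(atoms$chain)
  structure(list(atoms = atoms, xyz = xyz, box = box),
            class = "molecular_system")
}

.guess_element <- function(elety) {
  # PDB-style atom names: strip digits/primes, element is the leading
  # letter(s); two-letter elements relevant here: CL, NA, MG
  nm <- toupper(gsub("[0-9']", "", elety))
  ifelse(nm %in% c("CL", "NA", "MG", "ZN", "FE"), nm,
         substr(nm, 1, 1))
}

#' @export
print.molecular_system <- function(x, ...) {
  cat(sprintf("Molecular system: %d atoms, %d chains, %d frames%s\n",
              nrow(x$atoms), length(unique(x$atoms$chain)), n_frames(x),
              if (is.null(x$box)) "" else sprintf(", box %.1f x %.1f x %.1f A",
                                                  x$box[1], x$box[2], x$box[3])))
  res <- unique(paste(x$atoms$chain, x$atoms$resno))
  cat(sprintf("  %d residues; residue names: %s\n", length(res),
              paste(sort(unique(x$atoms$resid)), collapse = " ")))
  invisible(x)
}

#' Number of frames in a molecular system
#' @param system a `molecular_system`.
#' @return integer frame count.
#' @export
n_frames <- function(system) dim(system$xyz)[3]

#' Coordinates of one frame
#' @param system a `molecular_system`.
#' @param frame frame index (1-based).
#' @return `n_atoms x 3` matrix.
#' @export
frame_coords <- function(system, frame) {
  if (frame < 1 || frame > n_frames(system)) stop("frame out of range")
  system$xyz[, , frame, drop = TRUE]
}

#' Select atom indices by metadata
#'
#' All supplied filters are ANDed; each may be a character vector of
#' admissible values.
#'
#' @param system a `molecular_system`.
#' @param resid,elety,chain,element,resno optional filters on residue
#'   name, atom name, chain id, element symbol, residue number.
#' @param protein if TRUE, restrict to standard protein residues (i.e.
#'   exclude waters and ions).
#' @param heavy if TRUE, exclude hydrogens.
#' @return integer vector of atom indices.
#' @export
select_atoms <- function(system, resid = NULL, elety = NULL, chain = NULL,
                         element = NULL, resno = NULL,
                         protein = FALSE, heavy = FALSE) {
  a <- system$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(resid)) keep <- keep & a$resid %in% resid
  if (!is.null(elety)) keep <- keep & a$elety %in% elety
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(element)) keep <- keep & a$elesy %in% element
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (protein) keep <- keep & !a$resid %in% .nonprotein_resids
  if (heavy) keep <- keep & a$elesy != "H"
  which(keep)
}

.nonprotein_resids <- c("HOH", "WAT", "TIP", "SOL", "PO4", "CLA", "CL", "NA",
                        "SOD", "POT", "K", "MG")

#' Read a multi-model PDB file into a molecular system
#'
#' Parses MODEL/ENDMDL blocks (a single-model file gives one frame) via
#' bio3d, after validating that every frame carries the same atom roster;
#' a mismatch is an error naming the offending frame and atom.  An
#' orthorhombic CRYST1 record, when present, becomes the box.
#'
#' @param path PDB file path (optionally gzipped).
#' @return a `molecular_system`.  Attribute `"missing_atoms"` carries a
#'   report of standard backbone atoms absent from protein residues.
#' @export
read_ensemble <- function(path) {
  lines <- readLines(path)
  atom_lines <- grepl("^(ATOM  |HETATM)", lines)
  model_starts <- grep("^MODEL", lines)
  # roster check straight from the text records
  sig <- function(ls) paste(substr(ls, 13, 27))
  if (length(model_starts) > 1) {
    bounds <- c(model_starts, length(lines) + 1L)
    rosters <- lapply(seq_along(model_starts), function(i) {
      blk <- lines[bounds[i]:(bounds[i + 1] - 1)]
      sig(blk[grepl("^(ATOM  |HETATM)", blk)])
    })
    ref <- rosters[[1]]
    for (i in seq_along(rosters)[-1]) {
      if (!identical(rosters[[i]], ref)) {
        extra <- setdiff(rosters[[i]], ref)
        missing <- setdiff(ref, rosters[[i]])
        stop("atom roster mismatch in frame ", i, ": ",
             if (length(missing)) paste("missing", trimws(missing[1])) else "",
             if (length(extra)) paste(" unexpected", trimws(extra[1])) else "")
      }
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  nat <- nrow(pdb$atom)
  xyz <- array(NA_real_, dim = c(nat, 3, nrow(pdb$xyz)))
  for (f in seq_len(nrow(pdb$xyz)))
    xyz[, , f] <- matrix(pdb$xyz[f, ], ncol = 3, byrow = TRUE)
  box <- NULL
  cry <- grep("^CRYST1", lines, value = TRUE)
  if (length(cry)) {
    v <- as.numeric(c(substr(cry[1], 7, 15), substr(cry[1], 16, 24),
                      substr(cry[1], 25, 33)))
    if (all(is.finite(v)) && all(v > 1)) box <- v
  }
  atoms <- data.frame(
    eleno = pdb$atom$eleno, elety = pdb$atom$elety, resid = pdb$atom$resid,
    chain = ifelse(is.na(pdb$atom$chain), "A", pdb$atom$chain),
    resno = pdb$atom$resno,
    elesy = ifelse(is.na(pdb$atom$elesy) | pdb$atom$elesy == "",
                   .guess_element(pdb$atom$elety), pdb$atom$elesy)
  )
  sys <- molecular_system(atoms, xyz, box)
  attr(sys, "missing_atoms") <- .missing_backbone_report(sys)
  sys
}

.missing_backbone_report <- function(sys) {
  a <- sys$atoms
  prot <- a[!a$resid %in% .nonprotein_resids, , drop = FALSE]
  if (!nrow(prot)) return(data.frame())
  key <- unique(prot[, c("chain", "resno", "resid")])
  out <- list()
  for (i in seq_len(nrow(key))) {
    have <- prot$elety[prot$chain == key$chain[i] & prot$resno == key$resno[i]]
    miss <- setdiff(c("N", "CA", "C", "O"), have)
    if (length(miss))
      out[[length(out) + 1]] <- data.frame(chain = key$chain[i],
                                           resno = key$resno[i],
                                           resid = key$resid[i],
                                           missing = paste(miss, collapse = ","))
  }
  if (length(out)) do.call(rbind, out) else data.frame()
}

#' Write a molecular system as multi-model PDB
#'
#' Emits MODEL/ENDMDL blocks (one per frame), chain ids, 1-based residue
#' numbers, angstrom coordinates, and a CRYST1 record when a box is set.
#'
#' @param system a `molecular_system`.
#' @param path output path.
#' @param header optional character vector of REMARK lines (provenance:
#'   generator seed and parameters).
#' @return the path, invisibly.
#' @export
write_ensemble <- function(system, path, header = NULL) {
  stopifnot(inherits(system, "molecular_system"))
  a <- system$atoms
  con <- file(path, open = "wb")
  on.exit(close(con))
  wl <- function(s) writeLines(s, con, sep = "\n")
  if (!is.null(header)) wl(sprintf("REMARK   6 %s", header))
  if (!is.null(system$box))
    wl(sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
               system$box[1], system$box[2], system$box[3]))
  fmt_name <- function(n) {
    # PDB alignment rule: single-letter-element names start in column 14
    ifelse(nchar(n) >= 4, substr(n, 1, 4), sprintf(" %-3s", n))
  }
  names4 <- fmt_name(a$elety)
  for (f in seq_len(n_frames(system))) {
    wl(sprintf("MODEL     %4d", f))
    xyzf <- system$xyz[, , f]
    wl(sprintf("%-6s%5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
               ifelse(a$resid %in% .nonprotein_resids, "HETATM", "ATOM"),
               seq_len(nrow(a)), names4, substr(a$resid, 1, 3), a$chain,
               a$resno, xyzf[, 1], xyzf[, 2], xyzf[, 3], 1, 0, a$elesy))
    wl("ENDMDL")
  }
  wl("END")
  invisible(path)
}
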