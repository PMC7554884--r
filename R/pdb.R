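# PDB snapshot reading/writing and region-spec configuration.
#
# Scope is deliberately narrow: fixed-column ATOM/HETATM/MODEL/ENDMDL/CRYST1
# records, coordinates taken natively as Angstrom, one Frame per MODEL.
# Trajectory formats (GRO/XTC/DCD) are out of scope; analyses consume PDB
# snapshots extracted from an MD run.

.default_water_resnames <- c("HOH", "SOL", "WAT", "TIP3")

.two_letter_elements <- c("CL", "BR", "SE", "ZN", "FE", "MG", "MN", "NA", "CA")

empty_atoms <- function() {
  data.frame(name = character(), element = character(),
             resname = character(), resid = integer(),
             x = numeric(), y = numeric(), z = numeric(),
             stringsAsFactors = FALSE)
}

# Build a frame object; waters is a list of twn_water with unique indices.
twn_frame <- function(waters = list(), protein_atoms = empty_atoms(),
                      ligand_atoms = empty_atoms(), box = NULL,
                      frame_id = 1L) {
  idx <- vapply(waters, function(w) w$index, integer(1))
  if (anyDuplicated(idx)) stop("duplicate water indices in frame")
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3 || any(box <= 0))
      stop("box must be three positive lengths in Angstrom")
  }
  structure(list(waters = waters, protein_atoms = protein_atoms,
                 ligand_atoms = ligand_atoms, box = box,
                 frame_id = as.integer(frame_id)),
            class = "twn_frame")
}

#' @export
print.twn_frame <- function(x, ...) {
  cat(sprintf("<twn_frame %d: %d waters, %d protein atoms, %d ligand atoms%s>\n",
              x$frame_id, length(x$waters), nrow(x$protein_atoms),
              nrow(x$ligand_atoms),
              if (is.null(x$box)) "" else
                sprintf(", box %.1fx%.1fx%.1f A", x$box[1], x$box[2], x$box[3])))
  invisible(x)
}

# n x 9 coordinate matrix (O, H1, H2) over the frame's waters.
frame_water_matrix <- function(frame) {
  n <- length(frame$waters)
  W <- matrix(NA_real_, n, 9)
  for (k in seq_len(n)) W[k, ] <- as.vector(t(frame$waters[[k]]$pos))
  W
}

frame_water_indices <- function(frame) {
  vapply(frame$waters, function(w) w$index, integer(1))
}

.guess_element <- function(name, record) {
  nm <- toupper(gsub("^[0-9']+", "", trimws(name)))
  if (nchar(nm) == 0) return("")
  two <- substr(nm, 1, 2)
  if (record == "HETATM" && two %in% .two_letter_elements) return(two)
  substr(nm, 1, 1)
}

.parse_atom_record <- function(line, lineno) {
  record <- trimws(substr(line, 1, 6))
  name <- substr(line, 13, 16)
  resname <- trimws(substr(line, 18, 21))
  resid <- suppressWarnings(as.integer(substr(line, 23, 26)))
  xyz <- suppressWarnings(as.numeric(c(substr(line, 31, 38),
                                       substr(line, 39, 46),
                                       substr(line, 47, 54))))
  if (anyNA(xyz) || is.na(resid))
    stop(sprintf("malformed %s record at line %d", record, lineno))
  element <- toupper(trimws(substr(line, 77, 78)))
  if (element == "") element <- .guess_element(name, record)
  list(name = trimws(name), element = element, resname = resname,
       resid = resid, chain = substr(line, 22, 22),
       icode = substr(line, 27, 27), x = xyz[1], y = xyz[2], z = xyz[3])
}

.atoms_to_frame <- function(atoms, box, frame_id, water_resnames,
                            ligand_resnames) {
  if (nrow(atoms) == 0)
    return(twn_frame(box = box, frame_id = frame_id))
  is_water <- atoms$resname %in% water_resnames
  is_ligand <- !is_water & atoms$resname %in% ligand_resnames
  waters <- list()
  if (any(is_water)) {
    wat <- atoms[is_water, , drop = FALSE]
    key <- paste(wat$chain, wat$resid, wat$icode, wat$resname)
    widx <- 0L
    for (k in unique(key)) {
      grp <- wat[key == k, , drop = FALSE]
      o <- grp$element == "O"
      h <- grp$element == "H"
      if (nrow(grp) != 3 || sum(o) != 1 || sum(h) != 2)
        stop(sprintf(paste0("water residue %s %d must contain exactly one O ",
                            "and two H atoms (found %d atoms)"),
                     grp$resname[1], grp$resid[1], nrow(grp)))
      widx <- widx + 1L
      hs <- grp[h, , drop = FALSE]
      waters[[widx]] <- water_molecule(
        oxygen = unlist(grp[o, c("x", "y", "z")]),
        hydrogen1 = unlist(hs[1, c("x", "y", "z")]),
        hydrogen2 = unlist(hs[2, c("x", "y", "z")]),
        index = widx)
    }
  }
  cols <- c("name", "element", "resname", "resid", "x", "y", "z")
  lig <- atoms[is_ligand, cols, drop = FALSE]
  # protein side keeps heavy atoms of everything that is neither water nor
  # ligand; hydrogens there play no role in any downstream analysis
  prot <- atoms[!is_water & !is_ligand & atoms$element != "H", cols,
                drop = FALSE]
  rownames(lig) <- rownames(prot) <- NULL
  twn_frame(waters = waters, protein_atoms = prot, ligand_atoms = lig,
            box = box, frame_id = frame_id)
}

#' Read all frames from a (possibly multi-MODEL) PDB file
#'
#' Each MODEL record opens a new frame; files without MODEL records yield a
#' single frame. Residues whose name is in `water_resnames` are assembled
#' into rigid waters (exactly one O and two H required -- hydrogen positions
#' are needed for the pair-energy hydrogen-bond test and are never rebuilt).
#' Residues named in `ligand_resnames` become ligand atoms; all remaining
#' heavy atoms are kept as protein atoms. A CRYST1 record, if present,
#' provides the periodic box lengths.
#'
#' @param path PDB file path.
#' @param water_resnames residue names recognised as water.
#' @param ligand_resnames residue names recognised as ligand.
#' @return list of `twn_frame` objects, frame_id = MODEL number (1-based).
#' @export
read_frames <- function(path, water_resnames = .default_water_resnames,
                        ligand_resnames = character()) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("empty PDB file: ", path)
  box <- NULL
  cr <- grep("^CRYST1", lines)
  if (length(cr) > 0) {
    v <- suppressWarnings(as.numeric(c(substr(lines[cr[1]], 7, 15),
                                       substr(lines[cr[1]], 16, 24),
                                       substr(lines[cr[1]], 25, 33))))
    if (!anyNA(v) && all(v > 0)) box <- v
  }
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM") | grepl("^(ATOM|HETATM)", rec)
  model_starts <- grep("^MODEL", lines)
  frames <- list()
  if (length(model_starts) == 0) {
    atoms <- .parse_atoms(lines, which(is_atom))
    frames[[1]] <- .atoms_to_frame(atoms, box, 1L, water_resnames,
                                   ligand_resnames)
  } else {
    ends <- c(model_starts[-1] - 1L, length(lines))
    for (m in seq_along(model_starts)) {
      span <- model_starts[m]:ends[m]
      sel <- span[is_atom[span]]
      atoms <- .parse_atoms(lines, sel)
      frames[[m]] <- .atoms_to_frame(atoms, box, m, water_resnames,
                                     ligand_resnames)
    }
  }
  frames
}

.parse_atoms <- function(lines, sel) {
  if (length(sel) == 0) {
    a <- empty_atoms()
    a$chain <- character(0)
    a$icode <- character(0)
    return(a)
  }
  recs <- lapply(sel, function(i) .parse_atom_record(lines[i], i))
  do.call(rbind, lapply(recs, function(r)
    data.frame(r, stringsAsFactors = FALSE)))
}

#' Read a single frame from a PDB file
#'
#' @inheritParams read_frames
#' @param model which MODEL to return (1-based).
#' @return a `twn_frame`.
#' @export
parse_frame <- function(path, water_resnames = .default_water_resnames,
                        ligand_resnames = character(), model = 1L) {
  frames <- read_frames(path, water_resnames, ligand_resnames)
  if (model > length(frames))
    stop("file has ", length(frames), " model(s); requested ", model)
  frames[[model]]
}

.fmt_name <- function(name, element) {
  # atom name occupies columns 13-16; one-letter-element names start in 14
  if (nchar(element) >= 2 || nchar(name) >= 4) sprintf("%-4s", name)
  else sprintf(" %-3s", name)
}

.atom_line <- function(record, serial, name, resname, chain, resid, xyz,
                       element) {
  sprintf("%-6s%5d %s%1s%-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial %% 100000L, .fmt_name(name, element), "", resname,
          chain, resid %% 10000L, xyz[1], xyz[2], xyz[3], 1, 0,
          sprintf("%2s", element))
}

#' Write frames to a multi-MODEL PDB file
#'
#' Waters are written as HOH residues with atoms O/H1/H2, ligand atoms as
#' HETATM under their residue name, protein atoms as ATOM records. A box, if
#' present on the first frame, becomes a CRYST1 record.
#'
#' @param frames list of `twn_frame` (or a single frame).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_frames <- function(frames, path) {
  if (inherits(frames, "twn_frame")) frames <- list(frames)
  out <- character(0)
  if (!is.null(frames[[1]]$box)) {
    b <- frames[[1]]$box
    out <- c(out, sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
      b[1], b[2], b[3], 90, 90, 90))
  }
  multi <- length(frames) > 1
  for (fr in frames) {
    if (multi) out <- c(out, sprintf("MODEL     %4d", fr$frame_id))
    serial <- 0L
    emit <- function(record, name, resname, resid, xyz, element) {
      serial <<- serial + 1L
      .atom_line(record, serial, name, resname, " ", resid, xyz, element)
    }
    p <- fr$protein_atoms
    for (i in seq_len(nrow(p)))
      out <- c(out, emit("ATOM", p$name[i], p$resname[i], p$resid[i],
                         c(p$x[i], p$y[i], p$z[i]), p$element[i]))
    l <- fr$ligand_atoms
    for (i in seq_len(nrow(l)))
      out <- c(out, emit("HETATM", l$name[i], l$resname[i], l$resid[i],
                         c(l$x[i], l$y[i], l$z[i]), l$element[i]))
    for (w in fr$waters) {
      out <- c(out,
               emit("HETATM", "O", "HOH", w$index, w$pos[1, ], "O"),
               emit("HETATM", "H1", "HOH", w$index, w$pos[2, ], "H"),
               emit("HETATM", "H2", "HOH", w$index, w$pos[3, ], "H"))
    }
    if (multi) out <- c(out, "ENDMDL")
  }
  out <- c(out, "END")
  writeLines(out, path)
  invisible(path)
}

#' Write ring centers of mass as a pseudo-atom PDB
#'
#' One HETATM per ring at its center of mass, residue name = ring class
#' (R3..R6), for superposition graphics over a binding site.
#'
#' @param rings ring table from [rings_table()] or [analyze_frames()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ring_pdb <- function(rings, path) {
  tab <- rings_table(rings)
  out <- character(nrow(tab))
  for (i in seq_len(nrow(tab)))
    out[i] <- .atom_line("HETATM", i, "X", tab$ring_class[i], " ", i,
                         c(tab$x[i], tab$y[i], tab$z[i]), "X")
  writeLines(c(out, "END"), path)
  invisible(path)
}
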