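# Trajectory container and multi-frame readers/writers (multi-model PDB, XYZ).

#' Construct a trajectory object
#'
#' A trajectory is an ordered list of frames sharing one atom roster. Each
#' frame holds an `n_atoms x 3` coordinate matrix in Angstrom and, optionally,
#' orthorhombic box edge lengths. Frame times are `t_i = (i - 1) * timestep`.
#'
#' @param frames list of frames; each frame is a list with elements `coords`
#'   (numeric matrix, columns x/y/z, Angstrom) and `box` (length-3 positive
#'   numeric or `NULL`).
#' @param timestep time between consecutive frames in ns; must be positive.
#' @param elements character vector of element symbols, one per atom.
#' @return an object of class `trajectory`.
#' @export
new_trajectory <- function(frames, timestep, elements = NULL) {
  if (length(frames) == 0) {
    abort("a trajectory needs at least one frame", class = "vesitraj_malformed_trajectory")
  }
  if (!is.numeric(timestep) || length(timestep) != 1 || !is.finite(timestep) || timestep <= 0) {
    abort("`timestep` must be a single positive number (ns)", class = "vesitraj_bad_timestep")
  }
  n <- nrow(frames[[1]]$coords)
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    if (!is.matrix(fr$coords) || ncol(fr$coords) != 3) {
      abort(sprintf("frame %d: coordinates must be an n x 3 matrix", k),
        class = "vesitraj_malformed_trajectory")
    }
    if (nrow(fr$coords) != n) {
      abort(sprintf("frame %d has %d atoms but frame 1 has %d", k, nrow(fr$coords), n),
        class = "vesitraj_malformed_trajectory")
    }
    if (!all(is.finite(fr$coords))) {
      abort(sprintf("frame %d contains non-finite coordinates", k),
        class = "vesitraj_malformed_trajectory")
    }
    if (!is.null(fr$box)) {
      if (length(fr$box) != 3 || any(!is.finite(fr$box)) || any(fr$box <= 0)) {
        abort(sprintf("frame %d: box must be three positive edge lengths", k),
          class = "vesitraj_malformed_trajectory")
      }
    }
  }
  if (is.null(elements)) elements <- rep("C", n)
  if (length(elements) != n) {
    abort("`elements` must have one symbol per atom", class = "vesitraj_malformed_trajectory")
  }
  structure(
    list(frames = frames, timestep = timestep, atom_count = n,
         elements = as.character(elements)),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "<trajectory> %d frame(s), %d atoms, timestep %g ns (%.4g ns total)\n",
    n_frames(x), x$atom_count, x$timestep, (n_frames(x) - 1) * x$timestep
  ))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory a `trajectory` object.
#' @return integer frame count.
#' @export
n_frames <- function(trajectory) length(trajectory$frames)

#' Frame times in ns
#' @param trajectory a `trajectory` object.
#' @return numeric vector `t_i = (i - 1) * timestep`.
#' @export
frame_times <- function(trajectory) (seq_len(n_frames(trajectory)) - 1) * trajectory$timestep

frame_coords <- function(trajectory, i) trajectory$frames[[i]]$coords

#' Read a multi-frame coordinate file
#'
#' Supported dialects are multi-model PDB (`MODEL`/`ENDMDL` records, `CRYST1`
#' box if present) and XYZ (repeated count / comment / `element x y z`
#' blocks). Coordinates are returned in Angstrom; atom ordering is identical
#' across frames by contract.
#'
#' @param path file path.
#' @param format `"pdb"` or `"xyz"`.
#' @param timestep time between frames in ns.
#' @return a [new_trajectory()] object.
#' @export
read_trajectory <- function(path, format = c("pdb", "xyz"), timestep = 0.01) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "vesitraj_io_error")
  }
  format <- tryCatch(match.arg(format), error = function(e) {
    abort(sprintf("unsupported trajectory format: %s", format[1]),
      class = "vesitraj_unsupported_format")
  })
  lines <- readLines(path, warn = FALSE)
  parsed <- switch(format, pdb = parse_pdb(lines), xyz = parse_xyz(lines))
  new_trajectory(parsed$frames, timestep, elements = parsed$elements)
}

parse_pdb <- function(lines) {
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  is_model <- startsWith(lines, "MODEL")
  is_end <- startsWith(lines, "ENDMDL")
  cryst <- lines[startsWith(lines, "CRYST1")]
  box <- NULL
  if (length(cryst) > 0) {
    box <- as.numeric(c(
      substr(cryst[1], 7, 15), substr(cryst[1], 16, 24), substr(cryst[1], 25, 33)
    ))
    if (any(!is.finite(box)) || any(box <= 0)) box <- NULL
  }
  if (!any(is_atom)) {
    abort("no ATOM/HETATM records found", class = "vesitraj_malformed_trajectory")
  }
  # model id per line: 0 before any MODEL record means a single implicit model
  model_id <- cumsum(is_model)
  atom_lines <- lines[is_atom]
  atom_model <- model_id[is_atom]
  models <- split(atom_lines, atom_model)
  frames <- vector("list", length(models))
  elements <- NULL
  for (k in seq_along(models)) {
    ml <- models[[k]]
    xyz <- cbind(
      as.numeric(substr(ml, 31, 38)),
      as.numeric(substr(ml, 39, 46)),
      as.numeric(substr(ml, 47, 54))
    )
    if (any(!is.finite(xyz))) {
      abort(sprintf("model %d: unparseable coordinates", k),
        class = "vesitraj_malformed_trajectory")
    }
    colnames(xyz) <- c("x", "y", "z")
    if (is.null(elements)) {
      el <- trimws(substr(ml, 77, 78))
      fallback <- trimws(substr(ml, 13, 16))
      el[el == ""] <- substr(gsub("[^A-Za-z].*$", "", fallback[el == ""]), 1, 1)
      el[el == ""] <- "C"
      elements <- el
    }
    frames[[k]] <- list(coords = xyz, box = box)
  }
  n <- vapply(frames, function(f) nrow(f$coords), integer(1))
  if (length(unique(n)) != 1) {
    abort("models differ in atom count", class = "vesitraj_malformed_trajectory")
  }
  list(frames = frames, elements = elements)
}

parse_xyz <- function(lines) {
  lines <- lines[nzchar(trimws(lines)) | seq_along(lines) %in% integer(0)]
  frames <- list()
  elements <- NULL
  i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n <= 0) {
      abort(sprintf("line %d: expected an atom count", i),
        class = "vesitraj_malformed_trajectory")
    }
    if (i + 1 + n > length(lines)) {
      abort("truncated XYZ frame", class = "vesitraj_malformed_trajectory")
    }
    block <- lines[(i + 2):(i + 1 + n)]
    toks <- strsplit(trimws(block), "[[:space:]]+")
    el <- vapply(toks, `[[`, character(1), 1)
    xyz <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
    if (any(!is.finite(xyz))) {
      abort("unparseable XYZ coordinates", class = "vesitraj_malformed_trajectory")
    }
    colnames(xyz) <- c("x", "y", "z")
    if (is.null(elements)) elements <- el
    frames[[length(frames) + 1]] <- list(coords = xyz, box = NULL)
    i <- i + 2 + n
  }
  if (length(frames) == 0) {
    abort("no frames found in XYZ file", class = "vesitraj_malformed_trajectory")
  }
  n <- vapply(frames, function(f) nrow(f$coords), integer(1))
  if (length(unique(n)) != 1) {
    abort("XYZ frames differ in atom count", class = "vesitraj_malformed_trajectory")
  }
  list(frames = frames, elements = elements)
}

#' Write a trajectory to disk
#'
#' Emits deterministic, fixed-width records so that identical trajectories
#' always produce byte-identical files. PDB stores coordinates at 3 decimals,
#' XYZ at 6 decimals.
#'
#' @param trajectory a `trajectory` object.
#' @param path output file path.
#' @param format `"pdb"` or `"xyz"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path, format = c("pdb", "xyz")) {
  stopifnot(inherits(trajectory, "trajectory"))
  format <- tryCatch(match.arg(format), error = function(e) {
    abort(sprintf("unsupported trajectory format: %s", format[1]),
      class = "vesitraj_unsupported_format")
  })
  if (n_frames(trajectory) == 0) {
    abort("refusing to write an empty trajectory", class = "vesitraj_malformed_trajectory")
  }
  out <- switch(format,
    pdb = format_pdb(trajectory),
    xyz = format_xyz(trajectory)
  )
  ok <- tryCatch({ writeLines(out, path); TRUE }, error = function(e) FALSE,
    warning = function(w) FALSE)
  if (!ok) abort(sprintf("cannot write to %s", path), class = "vesitraj_io_error")
  invisible(path)
}

format_pdb <- function(trajectory) {
  el <- trajectory$elements
  serial <- seq_len(trajectory$atom_count) %% 100000
  name <- sprintf("%-4s", substr(paste0(el, seq_len(trajectory$atom_count) %% 100), 1, 4))
  out <- character(0)
  box <- trajectory$frames[[1]]$box
  if (!is.null(box)) {
    out <- c(out, sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1", box[1], box[2], box[3], 90, 90, 90
    ))
  }
  for (k in seq_len(n_frames(trajectory))) {
    co <- trajectory$frames[[k]]$coords
    out <- c(
      out,
      sprintf("MODEL     %4d", k),
      sprintf(
        "ATOM  %5d %s MOL A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        serial, name, serial %% 10000, co[, 1], co[, 2], co[, 3], substr(el, 1, 2)
      ),
      "ENDMDL"
    )
  }
  c(out, "END")
}

format_xyz <- function(trajectory) {
  el <- trajectory$elements
  out <- character(0)
  for (k in seq_len(n_frames(trajectory))) {
    co <- trajectory$frames[[k]]$coords
    out <- c(
      out,
      as.character(trajectory$atom_count),
      sprintf("frame %d", k),
      sprintf("%-3s %14.6f %14.6f %14.6f", el, co[, 1], co[, 2], co[, 3])
    )
  }
  out
}

#' Extract a subset of frames
#' @param trajectory a `trajectory` object.
#' @param idx integer frame indices (in order).
#' @return a `trajectory` with the selected frames; the timestep is preserved.
#' @export
subset_frames <- function(trajectory, idx) {
  new_trajectory(trajectory$frames[idx], trajectory$timestep, trajectory$elements)
}
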