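#' Trajectory container
#'
#' In-memory representation of a molecular trajectory: per-frame particle
#' positions (nm) in a periodic box, with a static topology mapping each
#' particle to a molecule, species tag, atom name and mass.
#'
#' @param times numeric vector of frame times (ns), strictly increasing.
#' @param coords numeric array `n_particles x 3 x n_frames` (nm).
#' @param box numeric length-3 box edges (nm). Only x and y are treated as
#'   periodic by the analysis layer; z is never wrapped.
#' @param topology data frame with columns `molecule_id`, `species`,
#'   `atom_name`, `mass` (one row per particle, masses > 0).
#' @return object of class `trajectory`.
#' @export
trajectory <- function(times, coords, box, topology) {
  if (length(dim(coords)) != 3L || dim(coords)[2] != 3L)
    stop_ld("coords must be an n_particles x 3 x n_frames array")
  n <- dim(coords)[1]; nf <- dim(coords)[3]
  if (length(times) != nf)
    stop_ld("length(times) (%d) != number of frames (%d)", length(times), nf)
  if (nf > 1 && any(diff(times) <= 0))
    stop_ld("frame times must be strictly increasing")
  if (length(box) != 3L || any(box <= 0))
    stop_ld("box must be three positive lengths (nm)")
  need <- c("molecule_id", "species", "atom_name", "mass")
  if (!all(need %in% names(topology)))
    stop_ld("topology must have columns: %s", paste(need, collapse = ", "))
  if (nrow(topology) != n)
    stop_ld("topology rows (%d) != particle count (%d)", nrow(topology), n)
  if (any(!is.finite(topology$mass)) || any(topology$mass <= 0))
    stop_ld("all masses must be finite and > 0")
  structure(list(times = as.numeric(times), coords = coords,
                 box = as.numeric(box), topology = topology),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d particles, %d frames, t = %.4g..%.4g ns\n",
              dim(x$coords)[1], dim(x$coords)[3],
              x$times[1], x$times[length(x$times)]))
  cat(sprintf("  box: %.3f x %.3f x %.3f nm; species: %s\n", x$box[1],
              x$box[2], x$box[3],
              paste(unique(x$topology$species), collapse = ", ")))
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[3]
n_particles <- function(traj) dim(traj$coords)[1]

#' Select particle indices by topology attributes
#'
#' @param traj a [trajectory] object.
#' @param species,molecule_id,atom_name optional filters; `NULL` matches all.
#' @return integer vector of particle indices.
#' @export
select_particles <- function(traj, species = NULL, molecule_id = NULL,
                             atom_name = NULL) {
  keep <- rep(TRUE, nrow(traj$topology))
  if (!is.null(species)) keep <- keep & traj$topology$species %in% species
  if (!is.null(molecule_id))
    keep <- keep & traj$topology$molecule_id %in% molecule_id
  if (!is.null(atom_name)) keep <- keep & traj$topology$atom_name %in% atom_name
  which(keep)
}

#' Mass-weighted centre of mass of a particle selection in one frame
#'
#' @param traj a [trajectory] object.
#' @param frame frame index (1-based).
#' @param selection integer particle indices (e.g. from [select_particles()]).
#' @return numeric length-3 position (nm).
#' @export
compute_com <- function(traj, frame, selection) {
  if (length(selection) == 0L) stop_ld("empty selection in compute_com")
  m <- traj$topology$mass[selection]
  xyz <- matrix(traj$coords[selection, , frame], ncol = 3L)
  as.numeric(colSums(xyz * (m / sum(m))))
}

#' Extract a membrane-normal z-trace for one molecule
#'
#' Per frame, `z = COM_z(molecule) - COM_z(reference)`, where the reference
#' selection (by default the phosphate species `"P"`, i.e. the membrane
#' centre defined by the lipid phosphate layer) is recomputed every frame.
#'
#' @param traj a [trajectory] object.
#' @param molecule_id molecule to trace.
#' @param reference_species species tag of the membrane-centre reference
#'   particles, or `NULL` with `reference_selection` given explicitly.
#' @param reference_selection explicit integer particle indices overriding
#'   `reference_species`.
#' @return data frame `time_ns`, `molecule_id`, `species`, `z_nm`.
#' @export
extract_ztrace <- function(traj, molecule_id, reference_species = "P",
                           reference_selection = NULL) {
  mol <- select_particles(traj, molecule_id = molecule_id)
  if (length(mol) == 0L) stop_ld("molecule_id %s not in topology",
                                 as.character(molecule_id))
  ref <- reference_selection %||%
    select_particles(traj, species = reference_species)
  if (length(ref) == 0L)
    stop_ld(paste0("reference species '%s' absent from topology; pass an ",
                   "explicit 'reference_selection'"), reference_species)
  nf <- n_frames(traj)
  z <- vapply(seq_len(nf), function(f)
    compute_com(traj, f, mol)[3] - compute_com(traj, f, ref)[3], numeric(1))
  data.frame(time_ns = traj$times, molecule_id = molecule_id,
             species = traj$topology$species[mol[1]], z_nm = z)
}

# ---- GRO ---------------------------------------------------------------

#' Write a trajectory as a (multi-frame) GRO file
#'
#' Coordinates in nm, fixed GRO precision (0.001 nm). A JSON sidecar
#' `<path>.json` records provenance and particle masses (GRO itself carries
#' none).
#'
#' @param traj a [trajectory] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gro <- function(traj, path) {
  topo <- traj$topology
  n <- n_particles(traj)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("leafletdyn frame, t= %.4f", traj$times[f]), con)
    writeLines(sprintf("%5d", n), con)
    lines <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     topo$molecule_id %% 100000L,
                     substr(topo$species, 1, 5),
                     substr(topo$atom_name, 1, 5),
                     seq_len(n) %% 100000L,
                     traj$coords[, 1, f], traj$coords[, 2, f],
                     traj$coords[, 3, f])
    writeLines(lines, con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", traj$box[1], traj$box[2],
                       traj$box[3]), con)
  }
  .write_sidecar(traj, path, "gro")
  invisible(path)
}

.write_sidecar <- function(traj, path, format, extra = list()) {
  meta <- c(list(
    source = basename(path), format = format,
    package = "leafletdyn",
    package_version = as.character(utils::packageVersion("leafletdyn")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    n_particles = n_particles(traj), n_frames = n_frames(traj),
    masses = traj$topology$mass,
    molecule_id = traj$topology$molecule_id,
    species = traj$topology$species,
    atom_name = traj$topology$atom_name,
    times_ns = traj$times, box_nm = traj$box), extra)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
}

.read_sidecar <- function(path) {
  sc <- paste0(path, ".json")
  if (file.exists(sc)) jsonlite::read_json(sc, simplifyVector = TRUE) else NULL
}

.read_gro <- function(path) {
  lines <- readLines(path)
  frames <- list(); times <- numeric(0); topo <- NULL; box <- NULL
  i <- 1L; f <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    f <- f + 1L
    title <- lines[i]
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(nat))
      stop_ld("GRO parse error at frame %d: bad atom count line", f)
    if (i + 1L + nat + 1L > length(lines))
      stop_ld("GRO file truncated in frame %d", f)
    at <- lines[(i + 2L):(i + 1L + nat)]
    if (!is.null(topo) && nat != nrow(topo))
      stop_ld("inconsistent atom count at frame %d (%d vs %d)", f, nat,
              nrow(topo))
    xyz <- cbind(as.numeric(substr(at, 21, 28)),
                 as.numeric(substr(at, 29, 36)),
                 as.numeric(substr(at, 37, 44)))
    if (any(!is.finite(xyz)))
      stop_ld("GRO parse error: non-numeric coordinates in frame %d", f)
    if (is.null(topo)) {
      topo <- data.frame(
        molecule_id = as.integer(substr(at, 1, 5)),
        species = trimws(substr(at, 6, 10)),
        atom_name = trimws(substr(at, 11, 15)),
        mass = 1, stringsAsFactors = FALSE)
    }
    boxv <- as.numeric(strsplit(trimws(lines[i + 2L + nat]),
                                "\\s+")[[1]])[1:3]
    box <- boxv
    tm <- regmatches(title, regexpr("t= *([-0-9.eE+]+)", title))
    times <- c(times, if (length(tm))
      as.numeric(sub("t= *", "", tm)) else f - 1)
    frames[[f]] <- xyz
    i <- i + nat + 3L
    while (i <= length(lines) && !nzchar(trimws(lines[i]))) i <- i + 1L
  }
  coords <- array(unlist(frames), dim = c(nrow(topo), 3L, length(frames)))
  sc <- .read_sidecar(path)
  if (!is.null(sc$masses)) topo$mass <- sc$masses
  trajectory(times = times, coords = coords, box = box, topology = topo)
}

# ---- DCD ---------------------------------------------------------------

#' Write trajectory coordinates as a CHARMM-format DCD file
#'
#' DCD stores coordinates in Angstrom by MD convention; values are converted
#' from nm on write and back on read. DCD carries no topology: pair it with a
#' single-frame GRO ([write_gro()] of frame 1) or rely on the JSON sidecar
#' this writer emits.
#'
#' @param traj a [trajectory] object.
#' @param path output `.dcd` path.
#' @return `path`, invisibly.
#' @export
write_dcd <- function(traj, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  nf <- n_frames(traj); nat <- n_particles(traj)
  rec <- function(writer) {
    tcon <- rawConnection(raw(0), "wb")
    writer(tcon)
    body <- rawConnectionValue(tcon); close(tcon)
    writeBin(length(body), con, size = 4L)
    writeBin(body, con)
    writeBin(length(body), con, size = 4L)
  }
  rec(function(c2) {
    writeChar("CORD", c2, nchars = 4L, eos = NULL)
    icntrl <- integer(20)
    icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
    icntrl[20] <- 24L
    writeBin(icntrl, c2, size = 4L)
  })
  rec(function(c2) {
    writeBin(1L, c2, size = 4L)
    writeChar(formatC("leafletdyn trajectory", width = 80, flag = "-"), c2,
              nchars = 80L, eos = NULL)
  })
  rec(function(c2) writeBin(nat, c2, size = 4L))
  for (f in seq_len(nf))
    for (d in 1:3)
      rec(function(c2) writeBin(as.numeric(traj$coords[, d, f]) * 10, c2,
                                size = 4L))
  .write_sidecar(traj, path, "dcd", extra = list(length_unit = "angstrom"))
  invisible(path)
}

.read_dcd <- function(path, topology_gro = NULL) {
  xyz <- bio3d::read.dcd(path, verbose = FALSE)
  nf <- nrow(xyz); nat <- ncol(xyz) / 3L
  sc <- .read_sidecar(path)
  topo <- NULL; box <- NULL; times <- NULL
  if (!is.null(topology_gro)) {
    top_traj <- .read_gro(topology_gro)
    topo <- top_traj$topology; box <- top_traj$box
  }
  if (!is.null(sc)) {
    if (is.null(topo))
      topo <- data.frame(molecule_id = sc$molecule_id, species = sc$species,
                         atom_name = sc$atom_name, mass = sc$masses,
                         stringsAsFactors = FALSE)
    box <- box %||% sc$box_nm
    times <- sc$times_ns
  }
  if (is.null(topo))
    stop_ld(paste0("DCD carries no topology: pass 'topology' (a single-frame",
                   " GRO path) or keep the writer's JSON sidecar next to it"))
  if (nrow(topo) != nat)
    stop_ld("topology atom count (%d) != DCD atom count (%d)", nrow(topo), nat)
  coords <- array(NA_real_, dim = c(nat, 3L, nf))
  for (f in seq_len(nf))
    coords[, , f] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE) / 10
  trajectory(times = times %||% (seq_len(nf) - 1), coords = coords,
             box = box %||% c(1, 1, 1) * max(coords, na.rm = TRUE),
             topology = topo)
}

# ---- PDB ---------------------------------------------------------------

.read_pdb_traj <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  nat <- nrow(pdb$atom)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  mass <- tryCatch(bio3d::atom2mass(pdb$atom$elety),
                   error = function(e) rep(1, nat),
                   warning = function(w) rep(1, nat))
  topo <- data.frame(molecule_id = pdb$atom$resno,
                     species = trimws(pdb$atom$resid),
                     atom_name = trimws(pdb$atom$elety),
                     mass = mass, stringsAsFactors = FALSE)
  coords <- array(NA_real_, dim = c(nat, 3L, nf))
  for (f in seq_len(nf))
    coords[, , f] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE) / 10  # A -> nm
  box <- if (!is.null(pdb$cryst1) && length(pdb$cryst1$abc) == 3 &&
             all(is.finite(pdb$cryst1$abc)) && all(pdb$cryst1$abc > 0))
    pdb$cryst1$abc / 10
  else apply(coords, 2, function(m) diff(range(m))) + 1
  trajectory(times = seq_len(nf) - 1, coords = coords, box = box,
             topology = topo)
}

# ---- TSV z-trace dialect ------------------------------------------------

#' Read / write the TSV z-trace interchange table
#'
#' Tab-separated with header `time_ns  molecule_id  species  z_nm` — the
#' package's plain-text interchange format for membrane-normal
#' centre-of-mass traces.
#'
#' @param ztraces data frame with those four columns.
#' @param path file path.
#' @return `read_ztrace_tsv`: the data frame; `write_ztrace_tsv`: `path`,
#'   invisibly.
#' @export
write_ztrace_tsv <- function(ztraces, path) {
  need <- c("time_ns", "molecule_id", "species", "z_nm")
  if (!all(need %in% names(ztraces)))
    stop_ld("z-trace table needs columns: %s", paste(need, collapse = ", "))
  write.table(ztraces[, need], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_ztrace_tsv
#' @export
read_ztrace_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("time_ns", "molecule_id", "species", "z_nm")
  if (!all(need %in% names(df)))
    stop_ld("not a z-trace TSV (need columns: %s)", paste(need, collapse = ", "))
  if (any(!is.finite(df$z_nm))) stop_ld("non-finite z values in %s", path)
  df
}

# ---- dispatcher ---------------------------------------------------------

#' Read a trajectory or z-trace table, auto-detecting the format
#'
#' Supported: multi-frame GRO (`.gro`), DCD (`.dcd`, topology from a
#' single-frame GRO via `topology` or from the writer's JSON sidecar),
#' multi-MODEL PDB (`.pdb`, Angstrom converted to nm), and the TSV z-trace
#' dialect (`.tsv`).
#'
#' @param path input file.
#' @param format force a format (`"gro"`, `"dcd"`, `"pdb"`, `"ztrace_tsv"`)
#'   instead of extension-based detection.
#' @param topology optional single-frame GRO path carrying the topology for
#'   DCD input.
#' @return a [trajectory] object, or a z-trace data frame for
#'   `ztrace_tsv`.
#' @export
read_trajectory <- function(path, format = NULL, topology = NULL) {
  if (!file.exists(path)) stop_ld("file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  format <- format %||% switch(ext, gro = "gro", dcd = "dcd", pdb = "pdb",
                               tsv = "ztrace_tsv", NULL)
  if (is.null(format))
    stop_ld("unknown extension '.%s'; supported formats: gro, dcd, pdb, ztrace_tsv",
            ext)
  switch(format,
         gro = .read_gro(path),
         dcd = .read_dcd(path, topology_gro = topology),
         pdb = .read_pdb_traj(path),
         ztrace_tsv = read_ztrace_tsv(path),
         stop_ld("unsupported format '%s' (gro, dcd, pdb, ztrace_tsv)", format))
}
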