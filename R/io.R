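# File formats: XYZ structures (Angstrom, converted to bohr), a bespoke
# cell file (lattice vectors + periodic flags + atoms, bohr), the AIM
# descriptor table, and result writers.

#' Read an XYZ structure file
#'
#' Standard two-line-header XYZ; coordinates are interpreted in Angstrom and
#' converted to bohr (1 Angstrom = 1.8897259886 bohr). XYZ implies a
#' non-periodic system.
#'
#' @param path File path.
#' @return A list with `atoms` (tibble: `element, x, y, z` in bohr) and
#'   `cell` (non-periodic [unit_cell()]).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("parse-error: XYZ file too short", call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("parse-error: line 1 must be the atom count", call. = FALSE)
  if (length(lines) < n + 2) {
    stop("parse-error: expected ", n, " atom lines", call. = FALSE)
  }
  rows <- lapply(seq_len(n) + 2L, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 4) stop("parse-error: line ", i, " malformed", call. = FALSE)
    list(element = f[1], x = as.numeric(f[2]), y = as.numeric(f[3]),
         z = as.numeric(f[4]))
  })
  atoms <- dplyr::bind_rows(rows)
  atoms$x <- atoms$x * .bohr_per_angstrom
  atoms$y <- atoms$y * .bohr_per_angstrom
  atoms$z <- atoms$z * .bohr_per_angstrom
  list(atoms = atoms, cell = unit_cell())
}

#' Read a cell file (lattice vectors, periodic flags, atoms; bohr)
#'
#' Format (whitespace-delimited, `#` comments allowed): three lines
#' `vx vy vz flag` giving the lattice vectors in bohr with a 0/1 periodic
#' flag, then one line with the atom count, then `symbol x y z` lines in
#' bohr.
#'
#' @param path File path.
#' @return A list with `atoms` (tibble, bohr) and `cell`.
#' @export
read_cellfile <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) < 5) stop("parse-error: cell file too short", call. = FALSE)
  vecs <- matrix(0, 3, 3); flags <- logical(3)
  for (i in 1:3) {
    f <- as.numeric(strsplit(lines[i], "\\s+")[[1]])
    if (length(f) != 4 || anyNA(f)) {
      stop("parse-error: lattice line ", i, " malformed", call. = FALSE)
    }
    vecs[i, ] <- f[1:3]; flags[i] <- f[4] != 0
  }
  n <- suppressWarnings(as.integer(lines[4]))
  if (is.na(n) || length(lines) < 4 + n) {
    stop("parse-error: bad atom count", call. = FALSE)
  }
  rows <- lapply(seq_len(n) + 4L, function(i) {
    f <- strsplit(lines[i], "\\s+")[[1]]
    list(element = f[1], x = as.numeric(f[2]), y = as.numeric(f[3]),
         z = as.numeric(f[4]))
  })
  list(atoms = dplyr::bind_rows(rows), cell = unit_cell(vecs, flags))
}

#' Read an AIM descriptor table
#'
#' Delimited text, one row per atom, columns
#' `index symbol x y z n q r3 r4 volume m rdamp` in atomic units (`#`
#' comments allowed). Cross-checks electron-count consistency
#' (`n = Z - q`) and, when a structure is supplied, the atom count.
#'
#' @param path File path.
#' @param structure Optional structure list (from [read_xyz()] /
#'   [read_cellfile()]) to validate against.
#' @return A validated atoms tibble ([aim_atoms()]).
#' @export
read_aim_table <- function(path, structure = NULL) {
  df <- utils::read.table(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  needed <- c("index", "symbol", "x", "y", "z", "n", "q", "r3", "r4",
              "volume", "m", "rdamp")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop("parse-error: AIM table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!is.null(structure) && nrow(df) != nrow(structure$atoms)) {
    stop("consistency-error: AIM table has ", nrow(df),
         " rows but the structure has ", nrow(structure$atoms), " atoms",
         call. = FALSE)
  }
  atoms <- tibble::tibble(
    element = df$symbol, x = df$x, y = df$y, z = df$z,
    n = df$n, q = df$q, r3 = df$r3, r4 = df$r4,
    volume = df$volume, m = df$m, rdamp = df$rdamp
  )
  aim_atoms(atoms)
}

#' Write an AIM descriptor table
#'
#' Inverse of [read_aim_table()]; full precision, whitespace-delimited.
#'
#' @param atoms Atoms tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_aim_table <- function(atoms, path) {
  df <- data.frame(index = seq_len(nrow(atoms)), symbol = atoms$element,
                   x = atoms$x, y = atoms$y, z = atoms$z, n = atoms$n,
                   q = atoms$q, r3 = atoms$r3, r4 = atoms$r4,
                   volume = atoms$volume, m = atoms$m, rdamp = atoms$rdamp)
  utils::write.table(format(df, digits = 17, trim = TRUE), path,
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-atom results as a delimited table
#'
#' Emits the per-atom polarizability types, static-tensor eigenvalues and
#' dispersion coefficients, with a method tag, in a plain-text table
#' suitable for force-field builders and diff tooling.
#'
#' @param result An `mclf_result` or `tsscs_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(result, path) {
  at <- result$atoms
  at <- dplyr::mutate(at, method = result$method, .before = 1)
  utils::write.table(format(as.data.frame(at), digits = 10, trim = TRUE),
                     path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a machine-readable result summary
#'
#' Key-value document (YAML-compatible) with the method tag, configuration,
#' and system-level quantities, intended to sit alongside the per-atom
#' table from [write_result_table()].
#'
#' @param result An `mclf_result` or `tsscs_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_summary <- function(result, path) {
  lines <- c(paste0("method: ", result$method),
             paste0("n_atoms: ", nrow(result$atoms)))
  if (inherits(result, "mclf_result")) {
    g <- glance(result)
    mol <- molecular_polarizability(result)
    lines <- c(lines,
      paste0("cutoff_bohr: ", result$config$cutoff),
      paste0("n_imfreqs: ", result$config$n_imfreqs),
      paste0("n_increments: ", result$config$n_increments),
      paste0("mixing_cf: ", result$config$mixing_cf),
      paste0("mbsp: ", result$config$mbsp),
      paste0("conduction_c: ", result$config$conduction_c),
      paste0("alpha_molecular_iso: ", format(g$alpha_molecular_iso, digits = 10)),
      paste0("alpha_ff_total: ", format(g$alpha_ff_total, digits = 10)),
      paste0("c6_molecular: ", format(g$c6_molecular, digits = 10)),
      "alpha_molecular_tensor:",
      paste0("  - [", apply(round(mol, 8), 1, paste, collapse = ", "), "]"))
  } else {
    lines <- c(lines,
      paste0("cutoff_bohr: ", result$cutoff),
      paste0("alpha_scs_total: ",
             format(sum(result$atoms$alpha_scs), digits = 10)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Run the full pipeline from input files
#'
#' Thin driver: reads a structure (XYZ or cell file) and an AIM table,
#' validates their consistency, and dispatches to [mclf()] or
#' [tsscs_screen()]. Deterministic given the configuration.
#'
#' @param structure_path Path to an XYZ or cell file.
#' @param aim_path Path to the AIM descriptor table.
#' @param method `"mclf"` or `"tsscs"`.
#' @param config [mclf_config()] parameters.
#' @param reference Reference table.
#' @return The result object of the chosen method.
#' @export
run_pipeline <- function(structure_path, aim_path, method = c("mclf", "tsscs"),
                         config = mclf_config(),
                         reference = read_reference_table()) {
  method <- match.arg(method)
  structure <- if (grepl("\\.xyz$", structure_path, ignore.case = TRUE)) {
    read_xyz(structure_path)
  } else {
    read_cellfile(structure_path)
  }
  atoms <- read_aim_table(aim_path, structure)
  if (method == "mclf") {
    mclf(atoms, cell = structure$cell, reference = reference, config = config)
  } else {
    tsscs_screen(atoms, cell = structure$cell, reference = reference,
                 cutoff = config$cutoff, n_imfreqs = config$n_imfreqs,
                 omega_scale = config$omega_scale)
  }
}
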