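# Atomic structures, eigenvalue records, XYZ i/o, neighbor lists, splits.
# Unit contract at every module boundary: coordinates in Angstrom, energies in eV.

.ELEMENTS <- c(H = 1L, He = 2L, Li = 3L, Be = 4L, B = 5L, C = 6L, N = 7L,
               O = 8L, F = 9L, Ne = 10L, Na = 11L, Mg = 12L, Al = 13L,
               Si = 14L, P = 15L, S = 16L, Cl = 17L, Ar = 18L, K = 19L,
               Ca = 20L, Br = 35L, I = 53L)

#' Map element symbols to atomic numbers (and back)
#'
#' @param symbols character vector of element symbols (e.g. "C", "Cl").
#' @return integer vector of atomic numbers.
#' @keywords internal
symbol_to_z <- function(symbols) {
  z <- .ELEMENTS[symbols]
  if (anyNA(z))
    stop("unknown element symbol(s): ",
         paste(unique(symbols[is.na(z)]), collapse = ", "))
  unname(z)
}

z_to_symbol <- function(z) {
  idx <- match(z, .ELEMENTS)
  if (anyNA(idx)) stop("no symbol for atomic number(s): ",
                       paste(unique(z[is.na(idx)]), collapse = ", "))
  names(.ELEMENTS)[idx]
}

#' Create an atomic structure
#'
#' A molecular geometry: atomic numbers plus Cartesian coordinates in
#' Angstrom. Open boundary conditions (no periodicity).
#'
#' @param elements integer vector of atomic numbers (all >= 1).
#' @param positions numeric N x 3 matrix of Cartesian coordinates in Angstrom.
#' @param id opaque identifier string.
#' @return an object of class \code{"atomic_structure"}.
#' @export
atomic_structure <- function(elements, positions, id = "") {
  elements <- as.integer(elements)
  positions <- matrix(as.numeric(positions), nrow = length(elements), ncol = 3)
  if (length(elements) < 1L) stop("structure needs at least one atom")
  if (any(elements < 1L)) stop("atomic numbers must be >= 1")
  if (!all(is.finite(positions))) stop("positions must be finite")
  if (length(elements) > 1L) {
    dmin <- min(dist(positions))
    if (dmin < 0.3)
      stop(sprintf("degenerate geometry: minimum interatomic distance %.3f A < 0.3 A",
                   dmin))
  }
  structure(list(elements = elements, positions = positions,
                 id = as.character(id)),
            class = "atomic_structure")
}

#' @export
print.atomic_structure <- function(x, ...) {
  cat(sprintf("<atomic_structure %s: %d atoms (%s)>\n",
              if (nzchar(x$id)) x$id else "?", length(x$elements),
              paste(z_to_symbol(x$elements), collapse = "")))
  invisible(x)
}

n_atoms <- function(structure) length(structure$elements)

#' Create an eigenvalue record
#'
#' Sorted target energies in eV padded to a fixed number of slots, with a
#' validity mask. Padding slots (mask FALSE) carry 0 and are never read;
#' all padding trails the valid slots.
#'
#' @param values numeric vector of energies in eV, length \code{n_max};
#'   valid entries ascending.
#' @param mask logical vector of length \code{n_max}; TRUE marks a real
#'   target, FALSE a padding slot.
#' @param n_occupied number of occupied levels among the valid slots.
#' @param level_tag level-of-theory tag, e.g. "base" or "high".
#' @param id molecule identifier.
#' @return an object of class \code{"eigen_record"}.
#' @export
eigen_record <- function(values, mask = rep(TRUE, length(values)),
                         n_occupied, level_tag = "base", id = "") {
  values <- as.numeric(values); mask <- as.logical(mask)
  if (length(values) != length(mask)) stop("values and mask lengths differ")
  nv <- sum(mask)
  if (nv > 0L) {
    if (any(which(mask) != seq_len(nv)))
      stop("padding slots must trail all valid slots")
    v <- values[mask]
    if (is.unsorted(v)) stop("valid entries must be ascending")
  }
  n_occupied <- as.integer(n_occupied)
  if (n_occupied < 0L || n_occupied > nv)
    stop("n_occupied must lie in [0, number of valid slots]")
  structure(list(values = values, mask = mask, n_occupied = n_occupied,
                 level_tag = as.character(level_tag), id = as.character(id)),
            class = "eigen_record")
}

#' @export
print.eigen_record <- function(x, ...) {
  cat(sprintf("<eigen_record %s [%s]: %d/%d valid, %d occupied>\n",
              if (nzchar(x$id)) x$id else "?", x$level_tag,
              sum(x$mask), length(x$mask), x$n_occupied))
  invisible(x)
}

#' Read a (multi-frame) XYZ file
#'
#' Standard dialect: an atom-count line, a free-form comment line (which may
#' carry \code{key=value} tokens such as \code{id=...}), then one
#' \code{Symbol x y z} row per atom. Coordinates are taken as Angstrom.
#'
#' @param path path to an XYZ file.
#' @return list of \code{atomic_structure}, one per frame (empty list for an
#'   empty file).
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  # drop trailing blank lines only
  while (length(lines) && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  out <- list(); i <- 1L; frame <- 0L
  while (i <= length(lines)) {
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1L)
      stop(sprintf("line %d: malformed atom count '%s'", i, lines[i]))
    if (i + 1L + nat > length(lines))
      stop(sprintf("line %d: frame declares %d atoms but file ends early", i, nat))
    comment <- lines[i + 1L]
    rows <- lines[(i + 2L):(i + 1L + nat)]
    toks <- strsplit(trimws(rows), "[[:space:]]+")
    sym <- character(nat); pos <- matrix(NA_real_, nat, 3)
    for (k in seq_len(nat)) {
      tk <- toks[[k]]
      if (length(tk) < 4L)
        stop(sprintf("line %d: expected 'Symbol x y z'", i + 1L + k))
      sym[k] <- tk[1L]
      xyz <- suppressWarnings(as.numeric(tk[2:4]))
      if (anyNA(xyz))
        stop(sprintf("line %d: non-numeric coordinate", i + 1L + k))
      pos[k, ] <- xyz
    }
    frame <- frame + 1L
    id <- .comment_field(comment, "id")
    out[[frame]] <- atomic_structure(symbol_to_z(sym), pos,
                                     id = if (is.na(id)) sprintf("frame%03d", frame) else id)
    i <- i + 2L + nat
  }
  out
}

.comment_field <- function(comment, key) {
  m <- regmatches(comment,
                  regexpr(paste0(key, "=[^[:space:]]+"), comment))
  if (length(m) == 0L) return(NA_character_)
  sub(paste0("^", key, "="), "", m)
}

#' Write structures to a multi-frame XYZ file
#'
#' Coordinates are printed with 8 decimals so a read/write round trip is
#' lossless well below 1e-6 Angstrom. The comment line carries
#' \code{id=...}.
#'
#' @param structures list of \code{atomic_structure} (a single structure is
#'   also accepted).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_xyz <- function(structures, path) {
  if (inherits(structures, "atomic_structure")) structures <- list(structures)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in structures) {
    writeLines(as.character(n_atoms(s)), con)
    writeLines(paste0("id=", if (nzchar(s$id)) s$id else "unnamed"), con)
    sym <- z_to_symbol(s$elements)
    writeLines(sprintf("%-2s %14.8f %14.8f %14.8f", sym,
                       s$positions[, 1], s$positions[, 2], s$positions[, 3]),
               con)
  }
  invisible(path)
}

#' Build a neighbor list within a distance cutoff
#'
#' All ordered pairs (a, b), a != b, with interatomic distance <= cutoff.
#' Open boundary; the list is symmetric by construction.
#'
#' @param structure an \code{atomic_structure}.
#' @param cutoff cutoff radius in Angstrom (> 0).
#' @return list with integer vectors \code{i}, \code{j} (1-based atom
#'   indices), numeric \code{d} (distances, Angstrom) and \code{cutoff};
#'   class \code{"neighbor_list"}.
#' @export
build_neighbor_list <- function(structure, cutoff) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    stop("cutoff must be a positive scalar (Angstrom)")
  n <- n_atoms(structure)
  if (n == 1L)
    return(structure(list(i = integer(), j = integer(), d = numeric(),
                          cutoff = cutoff), class = "neighbor_list"))
  dm <- as.matrix(dist(structure$positions))
  keep <- which(dm <= cutoff & row(dm) != col(dm))
  ii <- row(dm)[keep]; jj <- col(dm)[keep]
  structure(list(i = as.integer(ii), j = as.integer(jj), d = dm[keep],
                 cutoff = cutoff),
            class = "neighbor_list")
}

#' Deterministic train/validation/test split
#'
#' Sizes are the rounded validation and test fractions with the remainder
#' assigned to train; the shuffle is a pure function of \code{seed}.
#'
#' @param n_items number of items to split (>= 3).
#' @param fractions numeric length-3 vector (train, validation, test),
#'   positive, summing to 1.
#' @param seed integer seed.
#' @return list with integer index vectors \code{train}, \code{validation},
#'   \code{test} and the \code{seed}; class \code{"dataset_split"}.
#' @export
split_dataset <- function(n_items, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (n_items < 3L) stop("need at least 3 items to populate all splits")
  if (length(fractions) != 3L || any(fractions <= 0))
    stop("fractions must be 3 positive numbers")
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  n_val <- round(fractions[2] * n_items)
  n_test <- round(fractions[3] * n_items)
  n_train <- n_items - n_val - n_test
  if (min(n_train, n_val, n_test) < 1L)
    stop("fractions leave an empty split for n_items = ", n_items)
  perm <- with_seed(seed, sample.int(n_items))
  structure(list(train = perm[seq_len(n_train)],
                 validation = perm[n_train + seq_len(n_val)],
                 test = perm[n_train + n_val + seq_len(n_test)],
                 seed = as.integer(seed)),
            class = "dataset_split")
}

#' Evaluate code with a temporary RNG seed
#'
#' Runs \code{expr} under \code{set.seed(seed)} and restores the caller's
#' RNG state afterwards, so package functions are deterministic without
#' clobbering the user's stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Write eigenvalue records to a flat CSV table
#'
#' One row per record: \code{id, level_tag, n_occupied}, padded energies
#' \code{e_0..e_{n_max-1}} (eV) and mask columns \code{m_0..m_{n_max-1}}
#' (0/1).
#'
#' @param records list of \code{eigen_record} with a common slot count.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_eigen_table <- function(records, path) {
  if (inherits(records, "eigen_record")) records <- list(records)
  n_max <- length(records[[1]]$values)
  ev <- t(vapply(records, function(r) r$values, numeric(n_max)))
  mk <- t(vapply(records, function(r) as.integer(r$mask), integer(n_max)))
  df <- data.frame(id = vapply(records, `[[`, "", "id"),
                   level_tag = vapply(records, `[[`, "", "level_tag"),
                   n_occupied = vapply(records, `[[`, 0L, "n_occupied"))
  colnames(ev) <- sprintf("e_%d", seq_len(n_max) - 1L)
  colnames(mk) <- sprintf("m_%d", seq_len(n_max) - 1L)
  utils::write.csv(cbind(df, ev, mk), path, row.names = FALSE)
  invisible(path)
}

#' Read eigenvalue records from a CSV table written by write_eigen_table
#'
#' @param path CSV path.
#' @return list of \code{eigen_record}.
#' @export
read_eigen_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ecols <- grep("^e_", names(df)); mcols <- grep("^m_", names(df))
  lapply(seq_len(nrow(df)), function(r) {
    eigen_record(as.numeric(df[r, ecols]), as.logical(as.integer(df[r, mcols])),
                 n_occupied = df$n_occupied[r], level_tag = df$level_tag[r],
                 id = df$id[r])
  })
}
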