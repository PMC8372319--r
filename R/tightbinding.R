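# Synthetic data generation: a distance-decay tight-binding oracle that
# labels arbitrary H/C/N/O geometries with eigenvalue spectra in a DFT-like
# range (about -30 to +5 eV). The parameterization is a deliberately
# non-physical stand-in whose only job is to give every downstream stage
# (encoder, heads, delta corrector, spectra) targets with the right
# statistical structure: smooth matrix elements, sorted eigenvalues that can
# cross along conformational paths, variable state counts across compounds.

#' Tight-binding generator parameters
#'
#' One s-like orbital per H and four orbitals per C/N/O, element-wise
#' on-site energies, and an exponential distance-decay hopping between all
#' orbital pairs on different atoms within a cutoff.
#'
#' @param onsite named numeric vector of on-site energies in eV.
#' @param n_orbitals named integer vector of orbitals per element.
#' @param beta0 hopping prefactor in eV (negative).
#' @param zeta hopping decay length in 1/Angstrom (positive).
#' @param d0 reference bond length in Angstrom.
#' @param cutoff interaction cutoff in Angstrom (> d0).
#' @return list of class \code{"tb_params"}.
#' @export
tb_params <- function(onsite = c(H = -13.6, C = -11.4, N = -13.0, O = -14.8),
                      n_orbitals = c(H = 1L, C = 4L, N = 4L, O = 4L),
                      beta0 = -8.0, zeta = 1.8, d0 = 1.0, cutoff = 4.0) {
  stopifnot(beta0 < 0, zeta > 0, cutoff > d0, all(n_orbitals >= 1L))
  structure(list(onsite = onsite, n_orbitals = n_orbitals, beta0 = beta0,
                 zeta = zeta, d0 = d0, cutoff = cutoff),
            class = "tb_params")
}

.VALENCE <- c(H = 1L, C = 4L, N = 5L, O = 6L)

#' Tight-binding Hamiltonian of a structure
#'
#' Diagonal entries are the per-element on-site energies; every orbital pair
#' on atoms a != b with d_ab <= cutoff couples with
#' beta0 * exp(-zeta * (d_ab - d0)). Exactly symmetric by construction.
#'
#' @param structure an \code{atomic_structure} of H/C/N/O atoms.
#' @param params a \code{tb_params}.
#' @return symmetric numeric matrix (eV); dimension = total orbital count.
#' @export
tb_hamiltonian <- function(structure, params = tb_params()) {
  sym <- z_to_symbol(structure$elements)
  if (!all(sym %in% names(params$onsite)))
    stop("tight-binding parameters only cover: ",
         paste(names(params$onsite), collapse = ", "))
  norb <- params$n_orbitals[sym]
  tot <- sum(norb)
  atom_of <- rep(seq_along(sym), norb)
  H <- diag(rep(params$onsite[sym], norb), tot)
  if (length(sym) > 1L) {
    dm <- as.matrix(dist(structure$positions))
    for (a in seq_len(length(sym) - 1L)) for (b in (a + 1L):length(sym)) {
      d <- dm[a, b]
      if (d <= params$cutoff) {
        t_ab <- params$beta0 * exp(-params$zeta * (d - params$d0))
        H[atom_of == a, atom_of == b] <- t_ab
        H[atom_of == b, atom_of == a] <- t_ab
      }
    }
  }
  unname(H)
}

#' Tight-binding eigenvalues and occupation of a structure
#'
#' Eigenvalues ascending; the occupation is floor(valence electrons / 2)
#' with valence counts H 1, C 4, N 5, O 6 (closed-shell filling).
#'
#' @inheritParams tb_hamiltonian
#' @return list with \code{values} (ascending, eV) and \code{n_occupied}.
#' @export
tb_eigenvalues <- function(structure, params = tb_params()) {
  H <- tb_hamiltonian(structure, params)
  vals <- rev(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
  nel <- sum(.VALENCE[z_to_symbol(structure$elements)])
  list(values = vals, n_occupied = as.integer(nel %/% 2L))
}

#' High-level-of-theory shift parameters
#'
#' Emulates a quasiparticle (GW-like) correction on top of the base level:
#' occupied states move down by s_occ(N_a) = c0 + c1/N_a and virtual states
#' move up by s_virt(N_a) = c2 + c3/N_a, both in eV, smooth in the atom
#' count and strictly positive, so the gap always widens.
#'
#' @param c0,c1 occupied-shift coefficients (eV, eV*atoms).
#' @param c2,c3 virtual-shift coefficients (eV, eV*atoms).
#' @return list of class \code{"high_level_shift"}.
#' @export
high_level_shift <- function(c0 = 0.8, c1 = 2.0, c2 = 0.6, c3 = 1.5) {
  p <- structure(list(c0 = c0, c1 = c1, c2 = c2, c3 = c3),
                 class = "high_level_shift")
  if (shift_occ(p, 1L) <= 0 || shift_virt(p, 1L) <= 0)
    stop("shifts must be positive for all atom counts")
  p
}

shift_occ <- function(shift, n_atoms) shift$c0 + shift$c1 / n_atoms
shift_virt <- function(shift, n_atoms) shift$c2 + shift$c3 / n_atoms

#' Apply the synthetic high-level shift to an eigenvalue record
#'
#' Occupied valid entries are lowered by s_occ(N_a), virtual valid entries
#' raised by s_virt(N_a); mask and occupation are unchanged and the tag
#' becomes "high". Positive shifts widen the gap and never reorder.
#'
#' @param record a \code{"base"}-level \code{eigen_record}.
#' @param n_atoms atom count of the molecule the record belongs to.
#' @param shift a \code{high_level_shift}.
#' @return the shifted \code{eigen_record} with \code{level_tag = "high"}.
#' @export
apply_high_level_shift <- function(record, n_atoms, shift = high_level_shift()) {
  v <- record$values
  nv <- sum(record$mask)
  if (record$n_occupied > 0L)
    v[seq_len(record$n_occupied)] <-
      v[seq_len(record$n_occupied)] - shift_occ(shift, n_atoms)
  if (nv > record$n_occupied) {
    idx <- (record$n_occupied + 1L):nv
    v[idx] <- v[idx] + shift_virt(shift, n_atoms)
  }
  eigen_record(v, record$mask, record$n_occupied, level_tag = "high",
               id = record$id)
}

#' Select the learned energy window from a full spectrum
#'
#' Keeps eigenvalues at or above \code{window_low} up to and including the
#' state \code{states_above_homo} slots above the HOMO (e.g. 2 keeps through
#' LUMO+1). If more than \code{n_max} states survive, the \code{n_max}
#' highest-energy ones (closest to the frontier) are kept. The result is
#' padded and masked to \code{n_max} and the occupation recounted within the
#' window.
#'
#' @param values full ascending eigenvalue list (eV).
#' @param n_occupied occupied count in the full list.
#' @param window_low lower window edge in eV (-Inf keeps everything below
#'   the frontier bound).
#' @param states_above_homo how many states above the HOMO to keep.
#' @param n_max slot count of the output record.
#' @param level_tag,id passed through to the record.
#' @return an \code{eigen_record}.
#' @export
select_window <- function(values, n_occupied, window_low = -10,
                          states_above_homo = 2L, n_max,
                          level_tag = "base", id = "") {
  if (is.unsorted(values)) stop("values must be ascending")
  hi <- min(length(values), n_occupied + states_above_homo)
  keep <- which(values >= window_low & seq_along(values) <= hi)
  if (length(keep) == 0L)
    stop("no eigenvalues survive the energy window")
  if (length(keep) > n_max)            # drop the deepest states
    keep <- keep[(length(keep) - n_max + 1L):length(keep)]
  v <- values[keep]
  occ_in <- sum(keep <= n_occupied)
  pad <- n_max - length(keep)
  eigen_record(c(v, rep(0, pad)), c(rep(TRUE, length(keep)), rep(FALSE, pad)),
               n_occupied = occ_in, level_tag = level_tag, id = id)
}

#' Perturbed geometry ensemble
#'
#' Displaces every atom of the template by independent zero-mean Gaussian
#' noise of standard deviation \code{sigma} per Cartesian component,
#' resampling any frame that violates the 0.3 Angstrom minimum-distance
#' invariant (up to 100 tries per frame).
#'
#' @param template an \code{atomic_structure}.
#' @param n number of frames.
#' @param sigma per-component displacement standard deviation in Angstrom.
#' @param seed integer seed; the ensemble is a pure function of it.
#' @return list of \code{atomic_structure}.
#' @export
generate_geometries <- function(template, n, sigma, seed = 1L) {
  stopifnot(sigma >= 0, n >= 1)
  na <- n_atoms(template)
  with_seed(seed, {
    lapply(seq_len(n), function(k) {
      for (try in seq_len(100L)) {
        pos <- template$positions + matrix(stats::rnorm(3 * na, sd = sigma), na, 3)
        ok <- na == 1L || min(dist(pos)) >= 0.3
        if (ok)
          return(atomic_structure(template$elements, pos,
                                  id = sprintf("%s_p%04d", template$id, k)))
      }
      stop("resampling failed 100 times: sigma too large for template")
    })
  })
}

#' Linear interpolation path between two conformers
#'
#' @param a,b \code{atomic_structure}s with identical elements and atom
#'   order.
#' @param n_frames number of frames including both endpoints (>= 2).
#' @return list of \code{atomic_structure}.
#' @export
interpolate_path <- function(a, b, n_frames) {
  if (!identical(a$elements, b$elements))
    stop("endpoint structures must have the same elements and atom order")
  stopifnot(n_frames >= 2)
  lambda <- seq(0, 1, length.out = n_frames)
  lapply(seq_len(n_frames), function(k) {
    atomic_structure(a$elements,
                     (1 - lambda[k]) * a$positions + lambda[k] * b$positions,
                     id = sprintf("path%03d", k))
  })
}

# Canonical water-like template: O-H 0.96 A, 104.5 degree angle.
.water_template <- function() {
  ang <- 104.5 * pi / 180
  atomic_structure(c(8L, 1L, 1L),
                   rbind(c(0, 0, 0),
                         c(0.96, 0, 0),
                         c(0.96 * cos(ang), 0.96 * sin(ang), 0)),
                   id = "water")
}

# 6-atom two-fragment system used for the crossing path (dataset B): an
# O-H dimer whose bond is scanned, next to a C-N-C-H chain outside the
# tight-binding cutoff. Stretching the O-H bond sweeps its bonding level up
# through the flat lone-pair levels, producing (near-)crossings inside the
# window while the underlying matrix elements stay smooth.
.chain6_template <- function(bond1 = 1.0) {
  atomic_structure(c(8L, 1L, 6L, 7L, 6L, 1L),
                   rbind(c(0, 0, 0),
                         c(bond1, 0, 0),
                         c(0.00, 4.50, 0),
                         c(1.10, 4.75, 0),
                         c(2.20, 4.50, 0),
                         c(3.25, 4.75, 0)),
                   id = "chain6")
}

# Random H/C/N/O chain with jittered ~1.2 A spacing (datasets C/D).
.random_chain <- function(n_at, id, sigma = 0.08) {
  repeat {
    z <- sample(c(1L, 6L, 7L, 8L), n_at, replace = TRUE,
                prob = c(0.35, 0.35, 0.15, 0.15))
    x <- cumsum(c(0, stats::runif(n_at - 1L, 1.0, 1.45)))
    pos <- cbind(x, 0, 0) + matrix(stats::rnorm(3 * n_at, sd = sigma), n_at, 3)
    if (n_at == 1L || min(dist(pos)) >= 0.4)
      return(atomic_structure(z, pos, id = id))
  }
}

label_structures <- function(structures, params, window_low, states_above_homo,
                             n_max, level_tag = "base") {
  lapply(structures, function(s) {
    tb <- tb_eigenvalues(s, params)
    select_window(tb$values, tb$n_occupied, window_low = window_low,
                  states_above_homo = states_above_homo, n_max = n_max,
                  level_tag = level_tag, id = s$id)
  })
}

#' Bundle structures and eigenvalue records into a dataset
#'
#' @param structures list of \code{atomic_structure}.
#' @param records list of \code{eigen_record} (same length and order).
#' @return list of class \code{"ph_dataset"} with elements
#'   \code{structures}, \code{records}, \code{n_max}.
#' @export
ph_dataset <- function(structures, records) {
  stopifnot(length(structures) == length(records))
  structure(list(structures = structures, records = records,
                 n_max = length(records[[1]]$values)),
            class = "ph_dataset")
}

#' @export
print.ph_dataset <- function(x, ...) {
  cat(sprintf("<ph_dataset: %d molecules, n_max = %d, tags: %s>\n",
              length(x$structures), x$n_max,
              paste(unique(vapply(x$records, `[[`, "", "level_tag")),
                    collapse = "/")))
  invisible(x)
}

#' @export
length.ph_dataset <- function(x) length(x$structures)

#' Subset a dataset by molecule index
#'
#' @param dataset a \code{ph_dataset}.
#' @param idx integer indices of the molecules to keep.
#' @return a \code{ph_dataset} with the selected molecules.
#' @export
subset_dataset <- function(dataset, idx) {
  ph_dataset(dataset$structures[idx], dataset$records[idx])
}

#' Generate the four synthetic benchmark datasets
#'
#' All labels come from the tight-binding oracle; all randomness flows from
#' the single seed (sub-seeds are fixed offsets of it).
#' \describe{
#'   \item{A}{1000 perturbed water-like geometries (sigma 0.05 A); every
#'     molecule has 6 windowed eigenvalues. Single-molecule configuration
#'     ensemble.}
#'   \item{B}{a 50-frame path on a 6-atom hetero chain scanning one terminal
#'     bond through a frontier-level crossing inside the window; also carries
#'     a perturbed training ensemble around the path
#'     (\code{$train_pool}).}
#'   \item{C}{2000 random H/C/N/O chains of 2-12 atoms with variable
#'     windowed state counts (n_max 10, window -18 eV to LUMO+1).}
#'   \item{D}{dataset C labelled at both "base" and "high" levels
#'     (\code{$records} base, \code{$records_high} shifted).}
#' }
#'
#' @param seed integer master seed.
#' @param sizes named list overriding the ensemble sizes (elements
#'   \code{A}, \code{B_pool}, \code{C}), mainly to scale examples down.
#' @param params a \code{tb_params}.
#' @param shift a \code{high_level_shift} for dataset D.
#' @param only optional character vector naming the datasets to generate
#'   (e.g. \code{"A"} or \code{c("C", "D")}); others are omitted.
#' @return named list of \code{ph_dataset}s \code{A}, \code{B}, \code{C},
#'   \code{D} (restricted to \code{only} when given).
#' @export
make_benchmark_suite <- function(seed = 1L,
                                 sizes = list(A = 1000L, B_pool = 400L, C = 2000L),
                                 params = tb_params(),
                                 shift = high_level_shift(),
                                 only = NULL) {
  seed <- as.integer(seed)
  want <- function(x) is.null(only) || x %in% only
  out <- list()

  if (want("A")) {
    # A: water-like ensemble, all 6 orbitals inside a wide window
    geomA <- generate_geometries(.water_template(), sizes$A, sigma = 0.05,
                                 seed = seed)
    recA <- label_structures(geomA, params, window_low = -70,
                             states_above_homo = 2L, n_max = 6L)
    out$A <- ph_dataset(geomA, recA)
  }

  if (want("B")) {
    # B: bond-scan path with an engineered eigenvalue crossing in the window
    a <- .chain6_template(bond1 = 0.75)
    b <- .chain6_template(bond1 = 3.6)
    path <- interpolate_path(a, b, 50L)
    win_B <- list(window_low = -60, states_above_homo = 2L, n_max = 8L)
    recB <- label_structures(path, params, win_B$window_low,
                             win_B$states_above_homo, win_B$n_max)
    B <- ph_dataset(path, recB)
    # training pool: noisy copies of frames spread along the path
    poolg <- with_seed(seed + 101L, {
      lam <- stats::runif(sizes$B_pool)
      lapply(seq_len(sizes$B_pool), function(k) {
        base <- (1 - lam[k]) * a$positions + lam[k] * b$positions
        repeat {
          pos <- base + matrix(stats::rnorm(18, sd = 0.03), 6, 3)
          if (min(dist(pos)) >= 0.3) break
        }
        atomic_structure(a$elements, pos, id = sprintf("bpool%04d", k))
      })
    })
    B$train_pool <- ph_dataset(poolg,
                               label_structures(poolg, params, win_B$window_low,
                                                win_B$states_above_homo,
                                                win_B$n_max))
    out$B <- B
  }

  if (want("C") || want("D")) {
    # C: cross-compound chains with variable windowed state counts
    geomC <- with_seed(seed + 202L,
                       lapply(seq_len(sizes$C), function(k)
                         .random_chain(sample(2:12, 1L), sprintf("mol%05d", k))))
    recC <- label_structures(geomC, params, window_low = -18,
                             states_above_homo = 2L, n_max = 10L)
    if (want("C")) out$C <- ph_dataset(geomC, recC)
    if (want("D")) {
      # D: the same compounds at two levels of theory
      D <- ph_dataset(geomC, recC)
      D$records_high <- lapply(seq_along(geomC), function(k)
        apply_high_level_shift(recC[[k]], n_atoms(geomC[[k]]), shift))
      out$D <- D
    }
  }
  out
}
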