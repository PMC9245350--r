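#' Read an oxDNA topology file (classic dialect)
#'
#' Classic layout: a header line `n_nucleotides n_strands`, then one record
#' per nucleotide: `strand_id base 3'_neighbour 5'_neighbour`, neighbour
#' indices 0-based with -1 for termini. Strands are reconstructed by walking
#' the neighbour links from each 3' terminus, so the returned strand order
#' is 3'->5'. Indices are converted to the package's 1-based convention at
#' this boundary. Malformed input is rejected with the offending line
#' number, never silently repaired.
#'
#' @param path file path.
#' @return a [topology()] with base letters kept as annotations.
#' @export
read_oxdna_topology <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]
  if (length(hdr) != 2L || anyNA(suppressWarnings(as.integer(hdr)))) {
    stop("topology header (line 1) must be 'n_nucleotides n_strands'",
         call. = FALSE)
  }
  n <- as.integer(hdr[1]); n_strands <- as.integer(hdr[2])
  if (length(lines) - 1L != n) {
    stop("topology declares ", n, " nucleotides but has ", length(lines) - 1L,
         " records", call. = FALSE)
  }
  rec <- strsplit(trimws(lines[-1]), "[[:space:]]+")
  strand_id <- integer(n); base <- character(n)
  nb3 <- integer(n); nb5 <- integer(n)
  for (i in seq_len(n)) {
    r <- rec[[i]]
    if (length(r) != 4L) {
      stop("malformed nucleotide record at line ", i + 1L, call. = FALSE)
    }
    strand_id[i] <- as.integer(r[1]); base[i] <- r[2]
    nb3[i] <- as.integer(r[3]); nb5[i] <- as.integer(r[4])
    if (anyNA(c(strand_id[i], nb3[i], nb5[i]))) {
      stop("non-integer field at line ", i + 1L, call. = FALSE)
    }
  }
  if (length(unique(strand_id)) != n_strands) {
    stop("header declares ", n_strands, " strands but records use ",
         length(unique(strand_id)), call. = FALSE)
  }
  # neighbour symmetry: i's 5' neighbour must name i as its 3' neighbour
  for (i in seq_len(n)) {
    j <- nb5[i]
    if (j >= 0L) {
      if (j >= n || nb3[j + 1L] != i - 1L) {
        stop("broken neighbour symmetry at line ", i + 1L,
             " (nucleotide ", i - 1L, " -> ", j, ")", call. = FALSE)
      }
    }
  }
  # walk strands from each 3' terminus (nb3 == -1), 3'->5' order
  starts <- which(nb3 == -1L)
  visited <- logical(n)
  strands <- lapply(starts, function(s0) {
    run <- integer(0)
    i <- s0
    while (i >= 1L) {
      if (visited[i]) stop("cyclic strand detected at nucleotide ", i - 1L,
                           call. = FALSE)
      visited[i] <<- TRUE
      run <- c(run, i)
      i <- nb5[i] + 1L   # 0-based neighbour -> 1-based index; -1 -> 0 ends
    }
    run
  })
  if (!all(visited)) {
    stop("strand walk did not reach ", sum(!visited),
         " nucleotide(s); neighbour links are inconsistent", call. = FALSE)
  }
  bonds <- do.call(rbind, lapply(strands, function(s) {
    if (length(s) < 2L) NULL else cbind(s[-length(s)], s[-1])
  }))
  topology(n, strands = strands, bonds = bonds,
           base_annotations = base)
}

#' Write an oxDNA topology file (classic dialect)
#'
#' Inverse of [read_oxdna_topology()]: emits the header and per-nucleotide
#' records with 0-based neighbour indices in strand storage order.
#'
#' @param topo a [topology()] whose strands are in 3'->5' order.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_oxdna_topology <- function(topo, path) {
  n <- topo$n_particles
  base <- topo$base_annotations
  if (is.null(base)) base <- rep("A", n)
  nb3 <- rep(-1L, n); nb5 <- rep(-1L, n); strand_id <- integer(n)
  for (k in seq_along(topo$strands)) {
    s <- topo$strands[[k]]
    strand_id[s] <- k
    if (length(s) >= 2L) {
      nb5[s[-length(s)]] <- s[-1] - 1L
      nb3[s[-1]] <- s[-length(s)] - 1L
    }
  }
  lines <- c(paste(n, length(topo$strands)),
             paste(strand_id, base, nb3, nb5))
  writeLines(lines, path)
  invisible(path)
}

#' Read an oxDNA configuration file
#'
#' Layout: three header lines (`t = <time>`, `b = <box>`, `E = <energies>`)
#' then one record per nucleotide: position (3), backbone-base versor (3),
#' normal versor (3), velocity (3), angular velocity (3). Positions are
#' consumed; orientation vectors, velocities and the raw headers are kept as
#' opaque pass-through so files re-emit losslessly — this package never
#' simulates the oxDNA force field, it only reads bead coordinates to
#' evaluate collective variables.
#'
#' @param path file path.
#' @param topo the paired [topology()]; record count must match.
#' @return a [particle_config()] with attribute `oxdna` carrying the
#'   pass-through fields.
#' @export
read_oxdna_configuration <- function(path, topo) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L) stop("configuration file truncated: missing header",
                               call. = FALSE)
  header <- lines[1:3]
  body <- lines[-(1:3)]
  if (length(body) != topo$n_particles) {
    stop("configuration has ", length(body), " records; topology declares ",
         topo$n_particles,
         if (length(body) < topo$n_particles)
           paste0(" (record ", length(body) + 1L, " missing)") else "",
         call. = FALSE)
  }
  fields <- lapply(seq_along(body), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(body[i]), "[[:space:]]+")[[1]]))
    if (length(v) < 9L || anyNA(v[1:9]) || !all(is.finite(v))) {
      stop("malformed or non-finite record at line ", i + 3L, call. = FALSE)
    }
    v
  })
  mat <- do.call(rbind, fields)
  cfg <- particle_config(mat[, 1:3, drop = FALSE])
  attr(cfg, "oxdna") <- list(header = header,
                             extra = mat[, -(1:3), drop = FALSE])
  cfg
}

#' Write an oxDNA configuration file
#'
#' Re-emits a configuration read by [read_oxdna_configuration()], preserving
#' headers and orientation/velocity fields; for configurations that were
#' never oxDNA files, default headers and zero orientation/velocity fields
#' are written.
#'
#' @param config a [particle_config()].
#' @param path output path.
#' @param digits numeric precision of emitted fields.
#' @return `path`, invisibly.
#' @export
write_oxdna_configuration <- function(config, path, digits = 15) {
  ox <- attr(config, "oxdna")
  n <- n_particles(config)
  if (is.null(ox)) {
    ox <- list(header = c("t = 0", "b = 100 100 100", "E = 0 0 0"),
               extra = cbind(matrix(rep(c(1, 0, 0, 0, 0, 1), each = n), n),
                             matrix(0, n, 6L)))
  }
  mat <- cbind(config$positions, ox$extra)
  rows <- apply(mat, 1L, function(v) {
    paste(format(v, digits = digits, trim = TRUE, scientific = FALSE),
          collapse = " ")
  })
  writeLines(c(ox$header, rows), path)
  invisible(path)
}

#' Build a duplex topology from a sense-strand sequence
#'
#' Two complementary strands (the reverse complement forms strand 2), each
#' in 3'->5' storage order, with named end groups of `end_group_size`
#' nucleotides spanning both strands at each duplex end — the bead groups a
#' centre-of-mass distance CV should bias so that the bias bends the duplex
#' instead of tearing base pairs.
#'
#' @param sequence 5'->3' sense-strand sequence (string, spaces allowed).
#' @param end_group_size nucleotides per strand in each end group.
#' @return a [topology()] with groups `end_a`, `end_b`.
#' @export
duplex_topology <- function(sequence, end_group_size = 3L) {
  seq_chars <- strsplit(gsub("[^ACGTacgt]", "", sequence), "")[[1]]
  seq_chars <- toupper(seq_chars)
  n1 <- length(seq_chars)
  if (n1 < 2L) stop("sequence must have at least 2 nucleotides", call. = FALSE)
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  rev_comp <- rev(unname(comp[seq_chars]))
  n <- 2L * n1
  # store each strand 3'->5'; strand 1 is the reverse of the 5'->3' input
  strand1 <- seq_len(n1)
  strand2 <- n1 + seq_len(n1)
  bases <- c(rev(seq_chars), rev(rev_comp))
  k <- min(end_group_size, n1)
  # duplex end A holds strand1's 3' terminus paired with strand2's 5' end
  end_a <- c(strand1[seq_len(k)], strand2[n1 - seq_len(k) + 1L])
  end_b <- c(strand1[n1 - seq_len(k) + 1L], strand2[seq_len(k)])
  topology(n, strands = list(strand1, strand2),
           groups = list(end_a = sort(end_a), end_b = sort(end_b)),
           base_annotations = bases)
}
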