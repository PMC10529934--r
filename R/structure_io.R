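#' Read a PQR point-charge topology
#'
#' Parses the whitespace-delimited PQR dialect: `ATOM`/`HETATM` records
#' carrying, after the coordinates, a partial charge (e) and a radius (A).
#' The residue name of each record becomes the atom's `group` label, which
#' is how selections address charge groups (e.g. `"HM1"`, `"CAGE"`,
#' `"SOLV"`).
#'
#' @param path Path to a PQR file.
#' @return A tibble of atoms with columns `index` (0-based), `name`,
#'   `group`, `x`, `y`, `z` (A), `charge` (e), `radius` (A), in file order.
#' @examples
#' f <- tempfile(fileext = ".pqr")
#' writeLines("ATOM      1  OW  SOLV    1   0.000   0.000   3.000 -0.8340 1.6000", f)
#' read_pqr(f)
#' @export
read_pqr <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  keep <- grepl("^(ATOM|HETATM)", lines)
  if (!any(keep)) {
    return(empty_atoms())
  }
  idx_lines <- which(keep)
  rows <- lapply(seq_along(idx_lines), function(i) {
    ln <- idx_lines[i]
    toks <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    # record serial name resname [chain] resid x y z charge radius
    if (length(toks) < 10L) {
      stop(sprintf("malformed PQR record at line %d: expected >= 10 fields, got %d (is the charge column missing?)",
                   ln, length(toks)), call. = FALSE)
    }
    n <- length(toks)
    num <- suppressWarnings(as.numeric(toks[(n - 4L):n]))
    if (anyNA(num)) {
      stop(sprintf("malformed PQR record at line %d: non-numeric coordinate/charge/radius field", ln),
           call. = FALSE)
    }
    tibble(
      index = i - 1L, name = toks[3L], group = toks[4L],
      x = num[1L], y = num[2L], z = num[3L], charge = num[4L], radius = num[5L]
    )
  })
  dplyr::bind_rows(rows)
}

empty_atoms <- function() {
  tibble(
    index = integer(), name = character(), group = character(),
    x = double(), y = double(), z = double(),
    charge = double(), radius = double()
  )
}

#' Write atoms as a PQR file
#'
#' Inverse of [read_pqr()]: coordinates are written to 1e-3 A and charges
#' to 1e-4 e, the package's declared round-trip precision.
#'
#' @param atoms Atom tibble (as from [read_pqr()] or [gen_cage_system()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pqr <- function(atoms, path) {
  radius <- if ("radius" %in% names(atoms)) atoms$radius else rep(1.5, nrow(atoms))
  lines <- sprintf(
    "ATOM  %5d %-4s %-4s %4d %11.3f %11.3f %11.3f %9.4f %7.4f",
    atoms$index + 1L, atoms$name, atoms$group, atoms$index + 1L,
    atoms$x, atoms$y, atoms$z, atoms$charge, radius
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a multi-frame XYZ trajectory
#'
#' Positions come from the XYZ file; charges and group labels are joined
#' from `charge_map` by position in the record, so the XYZ atom order must
#' match the topology order. Frame times are taken from a `time=<ps>` token
#' on the comment line when present, otherwise `0, stride, 2*stride, ...`.
#'
#' @param path Multi-frame XYZ file (count line, comment line, then
#'   `element x y z` rows).
#' @param charge_map Atom tibble whose length equals the per-frame atom
#'   count; supplies `name`, `group`, `charge` per atom.
#' @param stride Time between frames in ps, used when the file carries no
#'   `time=` comments.
#' @return A trajectory: a long tibble with columns `frame` (0-based),
#'   `time` (ps), `index`, `name`, `group`, `x`, `y`, `z`, `charge`.
#' @export
read_xyz_trajectory <- function(path, charge_map, stride = 10) {
  stopifnot(file.exists(path), is.data.frame(charge_map))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!(seq_along(lines) > length(lines))] # no-op; keep as read
  pos <- 1L
  n_total <- length(lines)
  frames <- list()
  fi <- 0L
  while (pos <= n_total && nzchar(trimws(lines[pos]))) {
    n_at <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n_at)) {
      stop(sprintf("XYZ parse error at line %d: expected atom count", pos), call. = FALSE)
    }
    if (n_at != nrow(charge_map)) {
      stop(sprintf("frame %d has %d atoms but the charge map declares %d",
                   fi, n_at, nrow(charge_map)), call. = FALSE)
    }
    if (pos + 1L + n_at > n_total) {
      stop(sprintf("truncated XYZ frame %d starting at line %d", fi, pos), call. = FALSE)
    }
    comment <- lines[pos + 1L]
    tm <- regmatches(comment, regexpr("time=\\s*[-0-9.eE+]+", comment))
    t_ps <- if (length(tm) == 1L) {
      as.numeric(sub("time=\\s*", "", tm))
    } else {
      fi * stride
    }
    body <- lines[(pos + 2L):(pos + 1L + n_at)]
    toks <- strsplit(trimws(body), "\\s+")
    bad <- which(vapply(toks, length, 1L) < 4L)
    if (length(bad)) {
      stop(sprintf("XYZ parse error at line %d: expected 'element x y z'",
                   pos + 1L + bad[1L]), call. = FALSE)
    }
    xyz <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
    if (anyNA(xyz)) {
      stop(sprintf("non-numeric coordinate in XYZ frame %d", fi), call. = FALSE)
    }
    frames[[fi + 1L]] <- tibble(
      frame = fi, time = t_ps,
      index = charge_map$index, name = charge_map$name, group = charge_map$group,
      x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
      charge = charge_map$charge
    )
    fi <- fi + 1L
    pos <- pos + 2L + n_at
  }
  traj <- dplyr::bind_rows(frames)
  if (nrow(traj) && is.unsorted(unique(traj$time), strictly = TRUE)) {
    stop("frame times must be strictly increasing", call. = FALSE)
  }
  traj
}

#' Write a trajectory as multi-frame XYZ
#'
#' @param traj Long trajectory tibble (see [read_xyz_trajectory()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xyz_trajectory <- function(traj, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (f in sort(unique(traj$frame))) {
    fr <- traj[traj$frame == f, , drop = FALSE]
    writeLines(as.character(nrow(fr)), con)
    writeLines(sprintf("frame %d time=%.4f", f, fr$time[1L]), con)
    writeLines(sprintf("%-4s %12.4f %12.4f %12.4f", fr$name, fr$x, fr$y, fr$z), con)
  }
  invisible(path)
}

#' Extract the atoms of one trajectory frame
#'
#' @param traj Long trajectory tibble.
#' @param frame 0-based frame id.
#' @return Atom tibble for that frame.
#' @export
traj_frame <- function(traj, frame) {
  out <- traj[traj$frame == frame, , drop = FALSE]
  if (!nrow(out)) stop(sprintf("no frame %s in trajectory", frame), call. = FALSE)
  out
}

# ---- selection mini-language -------------------------------------------

# Grammar:
#   expr    := term ('or' term)*
#   term    := shell ('and' shell)*
#   shell   := unary ('within' NUM 'of' unary)?
#   unary   := 'not' unary | base
#   base    := '(' expr ')' | 'group' LABEL | 'name' LABEL
#            | 'index' N(:N)? | 'all'
# "A within R of B" keeps atoms of A whose minimum distance to any atom of
# B is <= R (closed boundary).

sel_tokenize <- function(expr) {
  pat <- "\\(|\\)|[^\\s()]+"
  m <- gregexpr(pat, expr, perl = TRUE)[[1]]
  if (m[1] == -1) character() else regmatches(expr, list(m))[[1]]
}

#' Resolve a selection expression on one frame of atoms
#'
#' The selection language addresses atoms by `group` label, atom `name`,
#' 0-based `index` (single or `lo:hi` range), combined with `and`, `or`,
#' `not`, parentheses, and a distance-shell clause
#' `"<sel> within R of <sel>"` whose boundary is closed (atoms at exactly
#' R are included). Example: `"group SOLV within 3.0 of group HM1"`.
#'
#' @param atoms Atom tibble for a single frame.
#' @param sel Selection expression string, or an integer vector of atom
#'   indices passed through unchanged.
#' @return Sorted integer vector of 0-based atom indices.
#' @export
resolve_selection <- function(atoms, sel) {
  if (is.numeric(sel)) {
    return(sort(unique(as.integer(sel))))
  }
  stopifnot(is.character(sel), length(sel) == 1L)
  toks <- sel_tokenize(sel)
  if (!length(toks)) stop("empty selection expression", call. = FALSE)
  env <- new.env(parent = emptyenv())
  env$toks <- toks
  env$pos <- 1L
  peek <- function() if (env$pos <= length(env$toks)) env$toks[env$pos] else NA_character_
  advance <- function() {
    tk <- peek()
    env$pos <- env$pos + 1L
    tk
  }
  expect <- function(what) {
    tk <- advance()
    if (is.na(tk) || tk != what) {
      stop(sprintf("selection parse error: expected '%s' near position %d in %s",
                   what, env$pos - 1L, dQuote(sel)), call. = FALSE)
    }
    tk
  }

  parse_base <- function() {
    tk <- advance()
    if (is.na(tk)) stop("selection parse error: unexpected end of expression", call. = FALSE)
    if (tk == "(") {
      v <- parse_expr()
      expect(")")
      return(v)
    }
    if (tk == "all") {
      return(rep(TRUE, nrow(atoms)))
    }
    if (tk == "group") {
      lab <- advance()
      if (!lab %in% atoms$group) {
        stop(sprintf("unknown group label %s; valid labels: %s",
                     dQuote(lab), paste(sort(unique(atoms$group)), collapse = ", ")),
             call. = FALSE)
      }
      return(atoms$group == lab)
    }
    if (tk == "name") {
      lab <- advance()
      if (!lab %in% atoms$name) {
        stop(sprintf("unknown atom name %s; valid names: %s",
                     dQuote(lab), paste(sort(unique(atoms$name)), collapse = ", ")),
             call. = FALSE)
      }
      return(atoms$name == lab)
    }
    if (tk == "index") {
      spec <- advance()
      if (grepl("^\\d+:\\d+$", spec)) {
        rg <- as.integer(strsplit(spec, ":")[[1]])
        return(atoms$index >= rg[1] & atoms$index <= rg[2])
      }
      if (grepl("^\\d+$", spec)) {
        return(atoms$index == as.integer(spec))
      }
      stop(sprintf("bad index specifier %s", dQuote(spec)), call. = FALSE)
    }
    stop(sprintf("selection parse error: unexpected token %s", dQuote(tk)), call. = FALSE)
  }

  parse_unary <- function() {
    if (identical(peek(), "not")) {
      advance()
      return(!parse_unary())
    }
    parse_base()
  }

  parse_shell <- function() {
    a <- parse_unary()
    if (identical(peek(), "within")) {
      advance()
      r <- suppressWarnings(as.numeric(advance()))
      if (is.na(r) || r < 0) stop("'within' needs a non-negative distance", call. = FALSE)
      expect("of")
      b <- parse_unary()
      if (!any(b)) return(rep(FALSE, nrow(atoms)))
      pa <- as.matrix(atoms[a, c("x", "y", "z")])
      pb <- as.matrix(atoms[b, c("x", "y", "z")])
      keep <- rep(FALSE, nrow(atoms))
      if (nrow(pa)) {
        d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
        keep[which(a)] <- sqrt(pmax(apply(d2, 1L, min), 0)) <= r
      }
      return(keep)
    }
    a
  }

  parse_term <- function() {
    v <- parse_shell()
    while (identical(peek(), "and")) {
      advance()
      v <- v & parse_shell()
    }
    v
  }

  parse_expr <- function() {
    v <- parse_term()
    while (identical(peek(), "or")) {
      advance()
      v <- v | parse_term()
    }
    v
  }

  mask <- parse_expr()
  if (env$pos <= length(env$toks)) {
    stop(sprintf("selection parse error: trailing tokens from %s",
                 dQuote(env$toks[env$pos])), call. = FALSE)
  }
  sort(atoms$index[mask])
}

sel_rows <- function(atoms, sel) {
  which(atoms$index %in% resolve_selection(atoms, sel))
}

# ---- reaction-axis frame ------------------------------------------------

#' Build the reaction-axis frame from Fe, O and a lateral reference
#'
#' Constructs the orthonormal right-handed frame used for all field and
#' dipole projections: `z_hat` points along Fe -> O (the reaction axis),
#' `y_hat` (the selectivity axis) is the component of the lateral
#' reference centroid direction orthogonal to `z_hat`, and
#' `x_hat = y_hat x z_hat`. The frame origin defaults to the Fe-O bond
#' midpoint, where field probes are also evaluated by default.
#'
#' @param atoms Atom tibble for one frame.
#' @param fe,o Selections resolving to exactly one atom each.
#' @param lateral_ref Selection (>= 1 atom, not collinear with Fe-O) whose
#'   centroid fixes the sign and direction of the y-axis. This choice is
#'   a convention; it is recorded in the returned object so reports can
#'   state it.
#' @param origin `"midpoint"` (default), `"fe"` or `"o"`.
#' @return An `axis_frame` object: list with `origin`, `x_hat`, `y_hat`,
#'   `z_hat` (3-vectors, A / unit), plus `fe_pos`, `o_pos`, `lateral_ref`.
#' @export
build_axis_frame <- function(atoms, fe = "group FE", o = "group O1",
                             lateral_ref = "group TLN",
                             origin = c("midpoint", "fe", "o")) {
  origin <- match.arg(origin)
  i_fe <- sel_rows(atoms, fe)
  i_o <- sel_rows(atoms, o)
  if (length(i_fe) != 1L) stop("'fe' must resolve to exactly one atom", call. = FALSE)
  if (length(i_o) != 1L) stop("'o' must resolve to exactly one atom", call. = FALSE)
  p_fe <- unlist(atoms[i_fe, c("x", "y", "z")], use.names = FALSE)
  p_o <- unlist(atoms[i_o, c("x", "y", "z")], use.names = FALSE)
  d <- p_o - p_fe
  if (norm3(d) < 0.5) {
    stop(sprintf("geometry error: Fe-O separation %.3f A is below 0.5 A", norm3(d)),
         call. = FALSE)
  }
  z_hat <- d / norm3(d)
  i_lat <- sel_rows(atoms, lateral_ref)
  if (!length(i_lat)) stop("'lateral_ref' selection is empty", call. = FALSE)
  cen <- colMeans(atoms[i_lat, c("x", "y", "z")])
  org <- switch(origin, midpoint = (p_fe + p_o) / 2, fe = p_fe, o = p_o)
  lat <- as.numeric(cen) - org
  y_raw <- lat - sum(lat * z_hat) * z_hat
  if (norm3(y_raw) < 1e-6) {
    stop("degenerate-frame error: lateral reference is collinear with the Fe-O axis",
         call. = FALSE)
  }
  y_hat <- y_raw / norm3(y_raw)
  x_hat <- cross3(y_hat, z_hat)
  structure(
    list(origin = org, x_hat = x_hat, y_hat = y_hat, z_hat = z_hat,
         fe_pos = p_fe, o_pos = p_o, lateral_ref = lateral_ref),
    class = "axis_frame"
  )
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @export
print.axis_frame <- function(x, ...) {
  cat("<axis_frame>\n")
  cat(sprintf("  origin: (%.3f, %.3f, %.3f) A\n", x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  z_hat (Fe->O): (%.4f, %.4f, %.4f)\n", x$z_hat[1], x$z_hat[2], x$z_hat[3]))
  cat(sprintf("  y_hat (lateral, ref %s): (%.4f, %.4f, %.4f)\n",
              dQuote(x$lateral_ref), x$y_hat[1], x$y_hat[2], x$y_hat[3]))
  invisible(x)
}
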