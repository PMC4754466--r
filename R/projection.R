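#' Project a tensor volume onto the medial surface (one subject)
#'
#' For every medially valid vertex, tensors are sampled by trilinear
#' interpolation at equally spaced points along the full chord
#' b_minus -> m -> b_plus (both spokes pooled, the skeleton point
#' included), FA is computed per sample, and the sample with the largest
#' FA is selected, TBSS-style. The returned MD is the MD of that selected
#' tensor, not the maximal MD. If the largest FA falls below `fa_min`
#' (default 0.2, excluding gray matter and CSF partial volume), the vertex
#' is recorded as missing for this subject, as it is when the spoke is
#' invalid or every sample leaves the volume. Out-of-bounds samples are
#' skipped, never zero-filled.
#'
#' Sampling density: `samples_per_spoke` points per half-spoke, densified
#' automatically so the step never exceeds half the smallest voxel
#' dimension, which keeps interpolation error well below measurement
#' noise. Ties in maximal FA are broken toward the sample nearest the
#' skeleton (deterministic, favors the medial locus).
#'
#' @param surface a [medial_surface()].
#' @param spokes matching [build_spokes()] result.
#' @param volume a [dt_volume()] in the same (template) space.
#' @param samples_per_spoke minimum samples per half-spoke (>= 3).
#' @param fa_min minimum acceptable FA (default 0.2).
#' @return data.frame with one row per vertex: `vertex`, `fa`, `md`
#'   (NA where missing).
#' @export
sample_max_fa <- function(surface, spokes, volume,
                          samples_per_spoke = 11L, fa_min = 0.2) {
  stopifnot(inherits(surface, "medial_surface"),
            inherits(spokes, "spoke_set"),
            inherits(volume, "dt_volume"))
  if (samples_per_spoke < 3L) stop("'samples_per_spoke' must be >= 3")
  nv <- nrow(surface$vertices)
  vox_min <- min(sqrt(colSums(volume$affine[1:3, 1:3]^2)))
  r <- surface$radius
  nhalf <- pmax(as.integer(samples_per_spoke),
                ceiling(r / (0.5 * vox_min)))

  # assemble every sample point, tagged by vertex and skeleton distance
  idx_list <- vector("list", nv)
  pt_list <- vector("list", nv)
  dist_list <- vector("list", nv)
  for (i in which(spokes$valid)) {
    f <- seq_len(nhalf[i]) / nhalf[i]
    m <- surface$vertices[i, ]
    pp <- outer(f, spokes$b_plus[i, ] - m) +
      matrix(m, nhalf[i], 3, byrow = TRUE)
    pm <- outer(f, spokes$b_minus[i, ] - m) +
      matrix(m, nhalf[i], 3, byrow = TRUE)
    pt_list[[i]] <- rbind(m, pp, pm)
    dist_list[[i]] <- c(0, f * r[i], f * r[i])
    idx_list[[i]] <- rep.int(i, 1L + 2L * nhalf[i])
  }
  pts <- do.call(rbind, pt_list)
  if (is.null(pts))
    return(data.frame(vertex = seq_len(nv), fa = NA_real_, md = NA_real_))
  vert <- unlist(idx_list, use.names = FALSE)
  dsk <- unlist(dist_list, use.names = FALSE)

  D6 <- interpolate_tensor(volume, pts)
  inb <- !is.na(D6[, 1])
  fa <- rep(NA_real_, nrow(D6))
  md <- rep(NA_real_, nrow(D6))
  if (any(inb)) {
    fa[inb] <- .fa_from_six(D6[inb, , drop = FALSE])
    md[inb] <- .md_from_six(D6[inb, , drop = FALSE])
  }

  out_fa <- rep(NA_real_, nv)
  out_md <- rep(NA_real_, nv)
  ok <- inb
  if (any(ok)) {
    # order by vertex, then FA descending, then skeleton distance:
    # the first row per vertex is the max-FA sample with medial tie-break
    o <- order(vert[ok], -fa[ok], dsk[ok])
    vo <- vert[ok][o]
    first <- o[!duplicated(vo)]
    sel_v <- vert[ok][first]
    sel_fa <- fa[ok][first]
    sel_md <- md[ok][first]
    keep <- sel_fa >= fa_min
    out_fa[sel_v[keep]] <- sel_fa[keep]
    out_md[sel_v[keep]] <- sel_md[keep]
  }
  data.frame(vertex = seq_len(nv), fa = out_fa, md = out_md)
}

#' Vertexwise measure set
#'
#' Per-subject, per-vertex FA and MD after projection. FA and MD are
#' missing together at any (subject, vertex).
#'
#' @param fa,md numeric subject x vertex matrices (rows named by subject).
#' @param subjects data.frame with columns `id`, `age`, `sex`.
#' @return object of class `vertex_measures`.
#' @export
vertex_measures <- function(fa, md, subjects) {
  fa <- as.matrix(fa); md <- as.matrix(md)
  if (!all(dim(fa) == dim(md)))
    stop("'fa' and 'md' must have identical dimensions")
  if (nrow(fa) != nrow(subjects))
    stop("one row per subject required")
  if (!all(is.na(fa) == is.na(md)))
    stop("fa and md must be missing together")
  structure(list(fa = fa, md = md, subjects = subjects),
            class = "vertex_measures")
}

#' @export
print.vertex_measures <- function(x, ...) {
  cat(sprintf("Vertex measures: %d subjects x %d vertices (%.1f%% missing)\n",
              nrow(x$fa), ncol(x$fa), 100 * mean(is.na(x$fa))))
  invisible(x)
}

#' Project a cohort of tensor volumes onto the surface
#'
#' Applies [sample_max_fa()] per subject and assembles a
#' [vertex_measures()] set. The per-subject missing-vertex fraction is
#' recorded in `attr(, "missing_fraction")` as a run log.
#'
#' @param surface,spokes,volumes,subjects the template surface, its
#'   spokes, a named list of [dt_volume()] (one per subject, in template
#'   space) and the subject table (`id`, `age`, `sex`).
#' @param ... passed to [sample_max_fa()].
#' @return a [vertex_measures()] object.
#' @export
project_cohort <- function(surface, spokes, volumes, subjects, ...) {
  if (nrow(subjects) == 0L) {
    nv <- nrow(surface$vertices)
    return(vertex_measures(matrix(numeric(0), 0, nv),
                           matrix(numeric(0), 0, nv), subjects))
  }
  if (is.null(names(volumes))) names(volumes) <- subjects$id
  if (!all(subjects$id %in% names(volumes)))
    stop("every subject needs a tensor volume")
  nv <- nrow(surface$vertices)
  fa <- matrix(NA_real_, nrow(subjects), nv,
               dimnames = list(subjects$id, NULL))
  md <- fa
  for (s in seq_len(nrow(subjects))) {
    res <- sample_max_fa(surface, spokes, volumes[[subjects$id[s]]], ...)
    fa[s, ] <- res$fa
    md[s, ] <- res$md
  }
  out <- vertex_measures(fa, md, subjects)
  attr(out, "missing_fraction") <-
    stats::setNames(rowMeans(is.na(fa)), subjects$id)
  out
}

#' Smooth projected measures on the surface
#'
#' Applies surface heat-kernel smoothing ([heat_smooth()]) to each
#' subject's projected FA and MD maps, the step performed between
#' projection and vertexwise fitting. Missing vertices stay missing.
#'
#' @param measures a [vertex_measures()].
#' @param surface the matching [medial_surface()].
#' @param fwhm kernel FWHM in mm (default 8).
#' @return a smoothed [vertex_measures()].
#' @export
smooth_measures <- function(measures, surface, fwhm = 8) {
  fa <- t(heat_smooth(surface, t(measures$fa), fwhm))
  md <- t(heat_smooth(surface, t(measures$md), fwhm))
  dimnames(fa) <- dimnames(measures$fa)
  dimnames(md) <- dimnames(measures$md)
  out <- vertex_measures(fa, md, measures$subjects)
  attr(out, "fwhm") <- fwhm
  out
}

#' Write / read vertex measures as long-format CSV
#'
#' Columns: subject_id, vertex_id, fa, md. Missing vertices are omitted.
#'
#' @param measures a [vertex_measures()]; `subjects` must accompany the
#'   CSV on read.
#' @param path CSV file path.
#' @export
write_measures_csv <- function(measures, path) {
  sub <- rep(rownames(measures$fa), times = ncol(measures$fa))
  vid <- rep(seq_len(ncol(measures$fa)), each = nrow(measures$fa))
  fa <- as.vector(measures$fa)
  md <- as.vector(measures$md)
  keep <- !is.na(fa)
  utils::write.csv(data.frame(subject_id = sub[keep], vertex_id = vid[keep],
                              fa = fa[keep], md = md[keep]),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measures_csv
#' @param subjects subject table matching the stored subject ids.
#' @param n_vertices vertex count of the surface the measures live on.
#' @export
read_measures_csv <- function(path, subjects, n_vertices) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  fa <- matrix(NA_real_, nrow(subjects), n_vertices,
               dimnames = list(subjects$id, NULL))
  md <- fa
  i <- match(df$subject_id, subjects$id)
  if (anyNA(i)) stop("CSV contains unknown subject ids")
  idx <- cbind(i, df$vertex_id)
  fa[idx] <- df$fa
  md[idx] <- df$md
  vertex_measures(fa, md, subjects)
}
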