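#' Quadric edge-collapse decimation
#'
#' Reduces the face count to approximately `target_faces` by collapsing the
#' cheapest edges under the Garland-Heckbert quadric error metric, with a
#' normal-preservation guard (collapses that would flip a face are skipped)
#' and boundary-constraint planes that keep the outline of open crops in
#' place. A mesh already at or below the target is returned unchanged.
#' Non-manifold or guard-blocked edges are skipped, so the achieved count is
#' reported in the `achieved_faces` attribute.
#'
#' @param mesh a clean [trimesh].
#' @param target_faces target face count (>= 4).
#' @return the decimated [trimesh] with attribute `achieved_faces`.
#' @export
decimate <- function(mesh, target_faces) {
  stopifnot_trimesh(mesh)
  if (target_faces < 4) stop("target_faces must be >= 4")
  if (nrow(mesh$faces) <= target_faces) {
    attr(mesh, "achieved_faces") <- nrow(mesh$faces)
    return(mesh)
  }
  res <- .decimate_cpp(mesh$vertices, mesh$faces, as.integer(target_faces))
  out <- trimesh(res$vertices, res$faces)
  if (res$achieved > ceiling(1.02 * target_faces))
    warning("decimation blocked early: achieved ", res$achieved,
            " faces for target ", target_faces)
  attr(out, "achieved_faces") <- res$achieved
  out
}
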