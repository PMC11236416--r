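#' Extract the spatial-temporal waveform patch of a unit
#'
#' Selects the channels in the rows `m_c - K_wf` to `m_c + K_wf` around the
#' peak channel, across both columns of the shank. For an interior peak with
#' the default `K_wf = 5` this yields 22 channels (11 rows x 2 columns); near
#' the probe ends only existing rows are kept and the patch is flagged
#' partial. Channels are ordered by (row offset, column) and keyed by their
#' offset so that patches from different units align positionally, i.e. the
#' comparison is peak-relative and therefore drift tolerant.
#'
#' @param waveform numeric matrix `[n_channels x n_samples]`, uV.
#' @param cm a [channel_map()].
#' @param peak_channel optional 0-based site index (defaults to the raw
#'   peak-to-peak argmax).
#' @param k_wf rows above/below the peak row (default 5).
#' @return numeric matrix `[n_patch_channels x n_samples]` with rownames
#'   `"<row_offset>:<column>"`; attributes `peak_channel` and `partial`.
#' @export
select_waveform_channels <- function(waveform, cm, peak_channel = NULL, k_wf = 5) {
  if (is.null(peak_channel)) {
    peak_channel <- cm$site_index[which.max(ptp_amplitude(waveform))]
  }
  sel <- neighborhood_sites(cm, peak_channel, k_wf)
  patch <- waveform[match(sel$site_index, cm$site_index), , drop = FALSE]
  rownames(patch) <- paste(sel$row_offset, sel$column_index, sep = ":")
  attr(patch, "peak_channel") <- peak_channel
  attr(patch, "partial") <- sel$partial[1]
  patch
}

#' Waveform distance between two units
#'
#' Normalized L2 metric over the aligned spatial-temporal patches: for each
#' channel present in both patches (matched by row offset and column relative
#' to each unit's own peak), the distance is
#' `L2(a_c - b_c) / max(L2(a_c), L2(b_c))`, and the result is the average over
#' the aligned channels (1/22 per channel for two interior patches). A
#' channel with zero energy in both patches contributes 0. Per-channel ratios
#' are clipped at 1 so the metric stays in `[0, 1]`.
#'
#' @param a,b waveform patches from [select_waveform_channels()].
#' @return scalar in `[0, 1]`; 0 iff the patches agree on every aligned
#'   channel.
#' @export
waveform_distance <- function(a, b) {
  keys <- intersect(rownames(a), rownames(b))
  if (length(keys) == 0L) stop("waveform patches share no aligned channels")
  aa <- a[keys, , drop = FALSE]
  bb <- b[keys, , drop = FALSE]
  na <- sqrt(rowSums(aa^2))
  nb <- sqrt(rowSums(bb^2))
  nd <- sqrt(rowSums((aa - bb)^2))
  mx <- pmax(na, nb)
  ratio <- ifelse(mx == 0, 0, nd / pmax(mx, .Machine$double.xmin))
  mean(pmin(ratio, 1))
}

#' Waveform distance matrix between two unit sets
#'
#' Vectorized [waveform_distance()] over all unit pairs: per aligned channel
#' offset the cross L2 terms are computed with one matrix product.
#'
#' @param patches1,patches2 lists of waveform patches.
#' @return matrix `[length(patches1) x length(patches2)]` of distances.
#' @export
waveform_distance_matrix <- function(patches1, patches2) {
  n1 <- length(patches1)
  n2 <- length(patches2)
  acc <- matrix(0, n1, n2)
  cnt <- matrix(0L, n1, n2)
  keys <- unique(c(unlist(lapply(patches1, rownames)),
                   unlist(lapply(patches2, rownames))))
  for (k in keys) {
    i1 <- which(vapply(patches1, function(p) k %in% rownames(p), TRUE))
    i2 <- which(vapply(patches2, function(p) k %in% rownames(p), TRUE))
    if (length(i1) == 0L || length(i2) == 0L) next
    A <- do.call(rbind, lapply(patches1[i1], function(p) p[k, ]))
    B <- do.call(rbind, lapply(patches2[i2], function(p) p[k, ]))
    na2 <- rowSums(A^2)
    nb2 <- rowSums(B^2)
    d2 <- pmax(outer(na2, nb2, "+") - 2 * tcrossprod(A, B), 0)
    mx <- outer(sqrt(na2), sqrt(nb2), pmax)
    ratio <- ifelse(mx == 0, 0, sqrt(d2) / pmax(mx, .Machine$double.xmin))
    acc[i1, i2] <- acc[i1, i2] + pmin(ratio, 1)
    cnt[i1, i2] <- cnt[i1, i2] + 1L
  }
  if (any(cnt == 0L)) stop("some unit pairs share no aligned channels")
  acc / cnt
}

#' Extract waveform patches for all units of a session
#'
#' @param bundle a [session_bundle()].
#' @param units a `unit_table` from [localize_units()]; patches are extracted
#'   for these units, centered on their recorded peak channels.
#' @param k_wf rows above/below the peak row.
#' @return named list (by unit id) of waveform patches.
#' @export
extract_patches <- function(bundle, units, k_wf = 5) {
  ids <- as.character(units$unit_id)
  out <- vector("list", length(ids))
  names(out) <- ids
  for (j in seq_along(ids)) {
    wf <- bundle$mean_waveforms[ids[j], , , drop = TRUE]
    out[[j]] <- select_waveform_channels(wf, bundle$channel_map,
                                         peak_channel = units$peak_channel[j],
                                         k_wf = k_wf)
  }
  out
}
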