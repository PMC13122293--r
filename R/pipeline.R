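# End-to-end reconstruction: IP + OOP series -> referenced susceptibility
# map, with or without fat-water separation.

#' Total-field estimation front end
#'
#' Registers the IP series onto the OOP series (translation only), corrects
#' bipolar phase offsets per series, merges the two echo trains, and
#' estimates the total field either without a fat model ("optw": Laplacian
#' unwrapping of successive phase differences + optimum-weights combination)
#' or with fat-water separation ("ideal": SNR-weighted R2*-IDEAL initialised
#' by the null field, ARLO R2* and two-point Dixon).
#'
#' @param ip,oop the two `echo_series`.
#' @param mask cord mask.
#' @param method "optw" or "ideal".
#' @param fat [fat_spectrum()] for the "ideal" method.
#' @param noise_region background region for per-echo SNR weights; `NULL`
#'   gives uniform weights.
#' @param register run translation registration of IP onto OOP.
#' @param correct_offsets run bipolar offset correction.
#' @param ... further arguments passed to [ideal_fit()].
#' @return list with `field` (total `field_map`), `merged` (the merged
#'   series), and for "ideal" additionally `r2s`, `wf`, `weights`,
#'   `converged`.
#' @export
sc_fit_field <- function(ip, oop, mask, method = c("optw", "ideal"),
                         fat = fat_spectrum(ip$B0), noise_region = NULL,
                         register = TRUE, correct_offsets = TRUE, ...) {
  method <- match.arg(method)
  if (register) ip <- register_translation(ip, oop)
  if (correct_offsets) {
    ip <- correct_bipolar_offsets(ip)
    oop <- correct_bipolar_offsets(oop)
  }
  merged <- merge_echo_series(ip, oop)
  if (method == "optw") {
    list(field = fit_field_optimum_weights(merged, mask), merged = merged)
  } else {
    wts <- if (is.null(noise_region)) NULL
           else compute_echo_weights(merged, mask, noise_region)
    r2s0 <- arlo_r2star(oop, mask)  # OOP grid is uniform from its first echo
    wf0 <- dixon_init(ip, oop, r2s0)
    fit <- ideal_fit(merged, fat = fat, weights = wts,
                     init = list(field0 = NULL, r2s0 = r2s0, wf0 = wf0),
                     mask = mask, ...)
    list(field = fit$field, merged = merged, r2s = fit$r2s, wf = fit$wf,
         weights = wts, converged = fit$converged,
         iterations = fit$iterations)
  }
}

#' Full spinal-cord QSM reconstruction
#'
#' Runs [sc_fit_field()], PDF background removal (optionally bypassed when
#' the field is known to contain no background sources), MEDI inversion with
#' the IP/OOP l2-norm anatomical image, and global-mean referencing.
#'
#' @param ip,oop the two `echo_series`.
#' @param mask cord mask.
#' @param method "optw" or "ideal".
#' @param lambda MEDI regularisation parameter.
#' @param noise_region optional background region for SNR weights.
#' @param background_removal set `FALSE` to treat the total field as local.
#' @param measured_mask region where the field is reliably measured, used as
#'   the PDF region of interest (external sources live outside it). Default
#'   `mask`; pass the full spinal canal (cord + CSF) when available, which
#'   mirrors the brain convention that background sources (bone, air) are
#'   unmeasured.
#' @param keep_fraction edge-mask keep fraction.
#' @param ... passed to [sc_fit_field()].
#' @return list with `chi` (referenced `susceptibility_map`), `field`,
#'   `local`, `anatomical`, plus the [sc_fit_field()] extras.
#' @export
sc_qsm_pipeline <- function(ip, oop, mask, method = c("optw", "ideal"),
                            lambda = 1e-3, noise_region = NULL,
                            background_removal = TRUE, measured_mask = NULL,
                            keep_fraction = 0.7, ...) {
  method <- match.arg(method)
  if (is.null(measured_mask)) measured_mask <- mask
  fit_mask <- mask | measured_mask
  ff <- sc_fit_field(ip, oop, fit_mask, method, noise_region = noise_region,
                     ...)
  kernel <- dipole_kernel(dim(mask), ip$voxel_size, ip$b0_direction)
  local <- if (background_removal) {
    pdf_remove(ff$field, measured_mask, kernel = kernel)
  } else {
    field_map(ff$field$value, mask & ff$field$mask, "local")
  }
  local <- field_map(local$value, mask & local$mask, "local")
  anat <- build_anatomical(ff$merged)
  em <- edge_mask(anat, mask, keep_fraction)
  chi <- medi_invert(local, edge = em, kernel = kernel, lambda = lambda,
                     B0 = ip$B0)
  chi <- reference_map(chi, mask)
  c(list(chi = chi, local = local, anatomical = anat), ff)
}
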