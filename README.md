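# mricascade

Reconstruction of accelerated 2-D multi-coil cardiac MR images by **cascaded
dual-domain convolutional networks with interleaved multi-coil data
consistency (MCDC)**, together with everything needed to exercise the method
end-to-end without any external dataset: multi-coil simulation from synthetic
cardiac phantoms, variable-density Cartesian undersampling, Walsh adaptive
coil combination and sensitivity estimation, compressed-sensing and
single-domain U-Net baselines, and SSIM/PSNR/RMSE evaluation.

## The problem and the method

Accelerated Cartesian MRI measures only a subset of phase-encode lines: with
`E` the line-sampling operator, `F` the 2-D Fourier transform and `S_i` the
sensitivity map of receiver coil `i`, the data are `x_i = E F (S_i m)` for an
unknown composite image `m`. Classical compressed sensing solves

    argmin_m  1/2 Σ_i ‖E F(S_i m) − x_i‖₂² + λ ‖W m‖₁

(here via ISTA with an orthonormal db4 wavelet `W`). The learned
reconstructors instead cascade two small U-Nets — **K-Net** trained on
composite k-space and **I-Net** trained on composite images — in either
order, with an MCDC operation after each:

* **KI-Net**: zero-filled composite k-space → K-Net → IFFT → MCDC → I-Net → MCDC
* **IK-Net**: zero-filled composite image → I-Net → MCDC → FFT → K-Net → IFFT → MCDC

MCDC expands a composite image to coil k-space through the sensitivity maps,
hard-replaces the sampled lines with the measured values coil by coil, and
recombines with the adaptive (matched-filter) combination. The subnetworks are
trained incrementally: stage 2 sees the data exactly as stage 1 + MCDC leaves
them, with stage 1 frozen. Training uses MSE loss, RMSProp (initial learning
rate 0.001, reduced 10× after 10 stale validation epochs), early stopping,
and an 80/20 by-volume train/validation split.

Because no external data are required, receiver coils are simulated by a
discretized Biot-Savart integral for a ring of circular loops, and cardiac-like
phantoms (bright blood pools, darker myocardial ring, chest wall; smooth
polynomial phase) are generated per seed. The fully sampled reference image
for both training labels and metrics is always the adaptive combination of the
fully sampled coil images.

## Worked example: zero-filled vs compressed sensing

```r
library(mricascade)

vol  <- simulate_volume(c(64, 64), n_coils = 8, n_frames = 1, seed = 42)
mask <- vd_mask(64, af_nominal = 2, seed = 7, nx = 64)
mask
#> <sampling_mask> ny=64, 32/64 lines sampled (achieved AF 2.00, nominal 2.00),
#>   center_fraction=0.0625, sigma=0.15, seed=7

mc   <- volume_frame(vol, 1)
acq  <- acquire(mc, mask)                       # retrospective undersampling
ref  <- adaptive_combine(mc$coil_images, vol$maps)
zf   <- zero_filled(acq, vol$maps)
cs   <- cs_reconstruct(acq, vol$maps, cs_config(lambda = 1e-3, n_iter = 60))

evaluate(list(zf), list(ref), method = "zero_filled", af = 2)
#> <eval_report> method=zero_filled AF=2 over 1 image(s)
#>   ssim     0.8491 +- 0.0000
#>   psnr_db  25.3817 +- 0.0000
#>   rmse     0.0538 +- 0.0000
evaluate(list(cs$image), list(ref), method = "cs", af = 2)
#> <eval_report> method=cs AF=2 over 1 image(s)
#>   ssim     0.9686 +- 0.0000
#>   psnr_db  36.6230 +- 0.0000
#>   rmse     0.0148 +- 0.0000
```

Halving the acquisition (AF = 2) drops the zero-filled SSIM to 0.85; the CS
baseline recovers most of the structure (SSIM 0.97, +11 dB PSNR). The ISTA
objective is guaranteed non-increasing — this run went from 1.614 to 0.397
over 60 iterations.

## Worked example: training an IK cascade

A desk-scale training (50 frames, `base_filters = 8`, 15 epochs per stage)
takes about two minutes on one CPU core:

```r
vols  <- lapply(1:5, function(v) simulate_volume(c(64, 64), 8, 10, seed = v))
ds    <- make_training_set(vols, af = 2, mask_seed = 100)
model <- train_cascade(ds, order = "IK",
                       tconf = train_config(max_epochs = 15, seed = 7),
                       uconf = unet_config(base_filters = 8))

test   <- make_training_set(simulate_volume(c(64, 64), 8, 10, seed = 99),
                            af = 2, mask_seed = 555)
recons <- lapply(test$examples,
                 function(e) ik_reconstruct(e$acquired, e$maps, model))
refs   <- lapply(test$examples, `[[`, "label_img")

evaluate(recons, refs, method = "ik", af = 2)
#> <eval_report> method=ik AF=2 over 10 image(s)
#>   ssim     0.8923 +- 0.0085
#>   psnr_db  28.9728 +- 0.4151
#>   rmse     0.0356 +- 0.0017
evaluate(lapply(test$examples, `[[`, "zf_img"), refs,
         method = "zero_filled", af = 2)
#> <eval_report> method=zero_filled AF=2 over 10 image(s)
#>   ssim     0.8281 +- 0.0108
#>   psnr_db  25.8318 +- 0.2894
#>   rmse     0.0511 +- 0.0017
```

Even this small run clears the zero-filled floor on every metric
(+0.06 SSIM, +3.1 dB, −30% RMSE on ten held-out frames); the shipped
experiments train on 100–200 frames. `model$history1`/`history2` hold the
per-epoch losses and learning rates, and `expected_lr_trace()` audits the
plateau schedule against the log.

## Command line

A thin CLI over the same functions lives in `inst/cli/mricascade.R`:

```sh
Rscript inst/cli/mricascade.R simulate --nx 64 --ny 64 --coils 8 \
        --frames 10 --volumes 5 --seed 1 --out data.h5
Rscript inst/cli/mricascade.R train --order ik --af 2 --data data.h5 \
        --seed 1 --epochs 30 --base-filters 8 --out model
Rscript inst/cli/mricascade.R reconstruct --method ik --model model \
        --data data.h5 --af 2 --mask-seed 9 --out report
Rscript inst/cli/mricascade.R make-mask --ny 256 --af 4 --seed 3 --out mask.txt
```

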