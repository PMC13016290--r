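# sceafunet

An R implementation of the **SCEAF-UNet** architecture for 2D medical image
segmentation: an encoder–decoder network whose skip connections are refined
by **edge attention fusion (EAF)** modules and whose decoder combines a
**multi-scale spatial attention gated block (MSAG)** with a **channel
attention modulation block (CAM)** through adaptive gated fusion. The
package is aimed at methods researchers who want to study, ablate and test
this architecture family end-to-end on a single CPU: it ships the full
training protocol, the evaluation metrics and paired statistics used for
segmentation benchmarking, a parameter/FLOP budgeting engine with ablation
sweeps, and a synthetic organ-phantom generator so that nothing needs to be
downloaded to train and evaluate.

The convolutional engine (forward passes and hand-derived backward passes,
AdamW, cosine schedule) is implemented in-package on compiled primitives,
so every equation of the architecture is explicit and testable.

## The model in brief

Encoder stages E1..E4 (any encoder honouring the contract
`H/2, H/4, H/8, H/16` with non-decreasing channels; a reference CNN is
included). Each skip is refined by an EAF module:

    S1  = DWConv3x3(F)                              # learned high-pass
    S2  = sigmoid(Conv1x1(GELU(Conv1x1(S1))))       # edge attention, C -> C/r -> C
    S   = GELU(BN(Conv1x1(concat(F, F ⊙ S2))))      # 2C -> C fusion
    out = GELU(BN(DWConv3x3(S)))

Decoder stages D4..D1 upsample with channel-shuffle blocks
`ReLU(CS(BN(DSConv9x9(UP(d; 2)))))`; at stages D3 and D2 the skip-fused
feature x and the refined skip g feed two branches — MSAG
(`Y = x_lat ⊙ A + x_lat ⊙ M`, with sigmoid gate A and tanh gate M derived
from multi-scale convolutions of g and x) and CAM
(`x + DropPath(γ ⊙ SE(Conv(GELU(Conv(GN(DWConv(x)))))))`) — fused by

    Out = ∂ ⊙ Y_MSAG + (1 − ∂) ⊙ Y_CAM,   ∂ = sigmoid(Y_MSAG)

Evaluation uses the Dice similarity coefficient
`DSC = 2|Mp ∩ Mg| / (|Mp| + |Mg|)` and the 95th-percentile symmetric
Hausdorff distance `HD95 = max(d95(R1, R2), d95(R2, R1))`, with paired
Wilcoxon signed-rank tests and bootstrap confidence intervals for method
comparison.

## Worked example

Train the small reference configuration on synthetic phantoms (64×64,
four classes: background, a large blob, a thin ring, a small ellipse) and
evaluate on the held-out split:

```r
library(sceafunet)

spec <- syntheticSpec()                 # 400/40/60 phantom cases, seed 1234
fit  <- runTraining(smallModelConfig(), smallTrainConfig(), spec = spec,
                    verbose = TRUE)
#> epoch 1/20 lr 0.00497 loss 0.7677 val DSC 0.3745
#> epoch 2/20 lr 0.00488 loss 0.3571 val DSC 0.5608
#> ...
#> epoch 19/20 lr 0.00003 loss 0.0210 val DSC 0.9768
#> epoch 20/20 lr 0.00000 loss 0.0205 val DSC 0.9757

pred <- lapply(fit$data$test,
               function(cs) predictSegmentation(fit$model, cs$image)$label)
gt   <- lapply(fit$data$test, function(cs) cs$label)
agg  <- aggregateRecords(evaluateSegmentation(pred, gt, classes = 1:3))
agg$perClass
#>   class       dsc      hd95  n hd95Excluded
#> 1     1 0.9903892 0.8989937 60            0
#> 2     2 0.9397754 0.8072351 60            3
#> 3     3 0.9797530 0.3619793 60            5
agg$meanDsc
#> [1] 0.9699725
```

The per-class rows are the large blob, the thin ring and the small ellipse;
`dsc` is the mean Dice over the 60 test cases (1 = perfect overlap), `hd95`
the mean 95th-percentile boundary distance in pixels (0 = boundaries
coincide), and `hd95Excluded` counts cases where the structure was absent
in both prediction and reference so the boundary distance is undefined.
Training used hybrid cross-entropy + soft-Dice loss, AdamW with a cosine
schedule, online rot90/flip/small-rotation augmentation and
best-validation-epoch selection — the full protocol at desk scale.

Budget accounting and ablation sweeps work on any configuration:

```r
countBudget(paperBudgetConfig())
#> Budget at 224x224 input (2 x multiply-accumulate over conv/linear layers)
#>   params: 17.4016 M   FLOPs: 11.3201 G   (MACs: 5.6600 G)
#>   backbone      16.6866 M params     9.1057 G FLOPs
#>   eaf            0.3357 M params     0.7101 G FLOPs
#>   decoder        0.2800 M params     0.8585 G FLOPs
#>   msag           0.0448 M params     0.2978 G FLOPs
#>   cam            0.0545 M params     0.3480 G FLOPs

ablationSweep("fusion")      # one row per fusion strategy
ablationSweep("placement")   # decoder-stage placement variants
```

A command-line wrapper with `synth`, `train`, `predict`, `evaluate`,
`count`, `ablate` and `compare` subcommands is installed at
`inst/scripts/sceaf-unet` (see `?sceafCli`).

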