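technique,model,accuracy,auroc
Base model,ResNet-34,88.72,78.51
Base model,MobileNetV3,92.99,94.81
Cutout,ResNet-34,90.24,93.25
Cutout,MobileNetV3,93.60,95.42
Random Erasing,ResNet-34,89.94,91.85
Random Erasing,MobileNetV3,90.85,92.19
MixUp,ResNet-34,89.94,96.13
MixUp,MobileNetV3,89.63,95.18
CutMix,ResNet-34,92.38,89.71
CutMix,MobileNetV3,92.68,96.90
Random Pixel Swap,ResNet-34,92.07,95.02
Random Pixel Swap,MobileNetV3,94.21,95.67
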