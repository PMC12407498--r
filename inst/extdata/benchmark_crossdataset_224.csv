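technique,model,accuracy,auroc
Base model,ResNet-34,82.53,84.33
Base model,MobileNetV3,91.24,90.03
Base model,ViT-B16,79.29,63.60
Base model,Swin-T,92.22,95.22
Cutout,ResNet-34,82.65,97.29
Cutout,MobileNetV3,92.09,90.70
Cutout,ViT-B16,81.80,63.49
Cutout,Swin-T,92.22,85.77
Random Erasing,ResNet-34,88.71,78.66
Random Erasing,MobileNetV3,91.45,89.66
Random Erasing,ViT-B16,82.65,58.92
Random Erasing,Swin-T,91.96,85.96
MixUp,ResNet-34,83.80,95.17
MixUp,MobileNetV3,91.58,90.36
MixUp,ViT-B16,80.74,52.24
MixUp,Swin-T,91.58,79.73
CutMix,ResNet-34,84.57,94.36
CutMix,MobileNetV3,90.69,80.26
CutMix,ViT-B16,81.12,66.90
CutMix,Swin-T,92.09,86.09
Random Pixel Swap,ResNet-34,90.69,97.48
Random Pixel Swap,MobileNetV3,92.35,93.30
Random Pixel Swap,ViT-B16,81.85,68.20
Random Pixel Swap,Swin-T,92.35,95.04
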