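technique,model,accuracy,auroc
Base model,ResNet-34,85.98,83.39
Base model,MobileNetV3,86.59,93.16
Base model,ViT-B16,57.62,64.88
Base model,Swin-T,85.67,89.06
Cutout,ResNet-34,85.67,86.11
Cutout,MobileNetV3,89.33,92.95
Cutout,ViT-B16,57.01,63.45
Cutout,Swin-T,85.37,93.68
Random Erasing,ResNet-34,82.62,91.23
Random Erasing,MobileNetV3,88.72,90.10
Random Erasing,ViT-B16,71.65,75.41
Random Erasing,Swin-T,86.89,91.42
MixUp,ResNet-34,84.45,91.05
MixUp,MobileNetV3,87.80,86.57
MixUp,ViT-B16,56.40,68.55
MixUp,Swin-T,88.41,92.51
CutMix,ResNet-34,85.67,88.34
CutMix,MobileNetV3,88.41,93.02
CutMix,ViT-B16,68.90,69.68
CutMix,Swin-T,88.41,92.05
Random Pixel Swap,ResNet-34,88.11,93.70
Random Pixel Swap,MobileNetV3,89.63,93.80
Random Pixel Swap,ViT-B16,73.17,74.64
Random Pixel Swap,Swin-T,89.94,94.79
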