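technique,model,accuracy,auroc
Base model,ResNet-34,96.83,99.25
Base model,MobileNetV3,93.02,98.27
Cutout,ResNet-34,96.51,99.35
Cutout,MobileNetV3,94.60,98.39
Random Erasing,ResNet-34,96.83,99.42
Random Erasing,MobileNetV3,93.65,98.82
MixUp,ResNet-34,92.38,98.64
MixUp,MobileNetV3,92.38,98.51
CutMix,ResNet-34,97.78,99.25
CutMix,MobileNetV3,94.60,98.61
Random Pixel Swap,ResNet-34,97.78,99.46
Random Pixel Swap,MobileNetV3,96.83,98.75
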