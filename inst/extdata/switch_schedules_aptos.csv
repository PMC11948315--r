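dataset,model,step,epoch,af
aptos,VGG16,1,1,ReLU
aptos,VGG16,2,11,SiLU
aptos,VGG16,3,16,ReLU
aptos,VGG16,4,28,Mish
aptos,VGG16,5,32,SiLU
aptos,VGG19,1,1,ReLU
aptos,VGG19,2,9,GELU
aptos,VGG19,3,15,ReLU
aptos,VGG19,4,23,Mish
aptos,VGG19,5,29,GELU
aptos,DenseNet121,1,1,ReLU
aptos,DenseNet121,2,3,GELU
aptos,DenseNet121,3,6,ReLU
aptos,DenseNet121,4,9,GELU
aptos,DenseNet121,5,14,Mish
aptos,DenseNet169,1,1,ReLU
aptos,DenseNet169,2,4,GELU
aptos,DenseNet169,3,9,ReLU
aptos,DenseNet169,4,11,GELU
aptos,DenseNet169,5,14,ReLU
aptos,EfficientNetV2B0,1,1,Mish
aptos,EfficientNetV2B0,2,2,ELU
aptos,EfficientNetV2B0,3,4,Mish
aptos,EfficientNetV2B0,4,6,ELU
aptos,EfficientNetV2B0,5,9,Mish
aptos,EfficientNetV2B1,1,1,Mish
aptos,EfficientNetV2B1,2,3,SiLU
aptos,EfficientNetV2B1,3,5,Mish
aptos,EfficientNetV2B1,4,8,ReLU
aptos,EfficientNetV2B1,5,11,SiLU
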