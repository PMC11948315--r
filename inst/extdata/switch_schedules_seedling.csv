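dataset,model,step,epoch,af
seedling,VGG16,1,1,GELU
seedling,VGG16,2,13,Mish
seedling,VGG16,3,15,SiLU
seedling,VGG16,4,17,Mish
seedling,VGG16,5,20,GELU
seedling,VGG19,1,1,Mish
seedling,VGG19,2,15,SiLU
seedling,VGG19,3,21,Mish
seedling,VGG19,4,27,GELU
seedling,VGG19,5,29,SiLU
seedling,DenseNet121,1,1,ReLU
seedling,DenseNet121,2,5,GELU
seedling,DenseNet121,3,11,ReLU
seedling,DenseNet121,4,15,GELU
seedling,DenseNet121,5,19,ReLU
seedling,DenseNet169,1,1,ReLU
seedling,DenseNet169,2,4,GELU
seedling,DenseNet169,3,8,ReLU
seedling,DenseNet169,4,11,GELU
seedling,DenseNet169,5,13,ReLU
seedling,EfficientNetV2B0,1,1,SiLU
seedling,EfficientNetV2B0,2,5,Mish
seedling,EfficientNetV2B0,3,9,ELU
seedling,EfficientNetV2B0,4,15,Mish
seedling,EfficientNetV2B0,5,17,ReLU
seedling,EfficientNetV2B1,1,1,SiLU
seedling,EfficientNetV2B1,2,4,ELU
seedling,EfficientNetV2B1,3,8,Mish
seedling,EfficientNetV2B1,4,11,ELU
seedling,EfficientNetV2B1,5,14,Mish
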