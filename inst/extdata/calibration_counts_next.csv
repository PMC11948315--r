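model,experiment,prev_af,af,count
VGG16,Exp1,SELU,ReLU,0
VGG16,Exp1,SELU,ELU,1
VGG16,Exp1,SELU,Mish,0
VGG16,Exp1,SELU,SiLU,0
VGG16,Exp1,SELU,GELU,0
VGG16,Exp1,ReLU,ELU,0
VGG16,Exp1,ReLU,SELU,0
VGG16,Exp1,ReLU,Mish,0
VGG16,Exp1,ReLU,SiLU,0
VGG16,Exp1,ReLU,GELU,0
VGG16,Exp1,Mish,ReLU,0
VGG16,Exp1,Mish,ELU,0
VGG16,Exp1,Mish,SELU,0
VGG16,Exp1,Mish,SiLU,0
VGG16,Exp1,Mish,GELU,0
VGG16,Exp2,ELU,ReLU,0
VGG16,Exp2,ELU,SELU,0
VGG16,Exp2,ELU,Mish,0
VGG16,Exp2,ELU,SiLU,0
VGG16,Exp2,ELU,GELU,0
VGG16,Exp2,SELU,ReLU,0
VGG16,Exp2,SELU,ELU,0
VGG16,Exp2,SELU,Mish,0
VGG16,Exp2,SELU,SiLU,0
VGG16,Exp2,SELU,GELU,0
VGG16,Exp2,ReLU,ELU,0
VGG16,Exp2,ReLU,SELU,0
VGG16,Exp2,ReLU,Mish,0
VGG16,Exp2,ReLU,SiLU,0
VGG16,Exp2,ReLU,GELU,0
VGG16,Exp3,ReLU,ELU,0
VGG16,Exp3,ReLU,SELU,0
VGG16,Exp3,ReLU,Mish,0
VGG16,Exp3,ReLU,SiLU,0
VGG16,Exp3,ReLU,GELU,0
VGG16,Exp3,GELU,ReLU,0
VGG16,Exp3,GELU,ELU,0
VGG16,Exp3,GELU,SELU,0
VGG16,Exp3,GELU,Mish,0
VGG16,Exp3,GELU,SiLU,0
VGG16,Exp3,ELU,ReLU,0
VGG16,Exp3,ELU,SELU,0
VGG16,Exp3,ELU,Mish,0
VGG16,Exp3,ELU,SiLU,0
VGG16,Exp3,ELU,GELU,0
DenseNet121,Exp1,GELU,ReLU,0
DenseNet121,Exp1,GELU,ELU,2
DenseNet121,Exp1,GELU,SELU,3
DenseNet121,Exp1,GELU,Mish,1
DenseNet121,Exp1,GELU,SiLU,0
DenseNet121,Exp1,ReLU,ELU,4
DenseNet121,Exp1,ReLU,SELU,2
DenseNet121,Exp1,ReLU,Mish,2
DenseNet121,Exp1,ReLU,SiLU,3
DenseNet121,Exp1,ReLU,GELU,2
DenseNet121,Exp1,SiLU,ReLU,0
DenseNet121,Exp1,SiLU,ELU,0
DenseNet121,Exp1,SiLU,SELU,0
DenseNet121,Exp1,SiLU,Mish,0
DenseNet121,Exp1,SiLU,GELU,0
DenseNet121,Exp2,GELU,ReLU,0
DenseNet121,Exp2,GELU,ELU,1
DenseNet121,Exp2,GELU,SELU,4
DenseNet121,Exp2,GELU,Mish,0
DenseNet121,Exp2,GELU,SiLU,0
DenseNet121,Exp2,ReLU,ELU,2
DenseNet121,Exp2,ReLU,SELU,3
DenseNet121,Exp2,ReLU,Mish,4
DenseNet121,Exp2,ReLU,SiLU,1
DenseNet121,Exp2,ReLU,GELU,2
DenseNet121,Exp2,SiLU,ReLU,0
DenseNet121,Exp2,SiLU,ELU,2
DenseNet121,Exp2,SiLU,SELU,3
DenseNet121,Exp2,SiLU,Mish,0
DenseNet121,Exp2,SiLU,GELU,0
DenseNet121,Exp3,ReLU,ELU,3
DenseNet121,Exp3,ReLU,SELU,3
DenseNet121,Exp3,ReLU,Mish,4
DenseNet121,Exp3,ReLU,SiLU,2
DenseNet121,Exp3,ReLU,GELU,2
DenseNet121,Exp3,Mish,ReLU,0
DenseNet121,Exp3,Mish,ELU,1
DenseNet121,Exp3,Mish,SELU,0
DenseNet121,Exp3,Mish,SiLU,0
DenseNet121,Exp3,Mish,GELU,0
DenseNet121,Exp3,GELU,ReLU,0
DenseNet121,Exp3,GELU,ELU,4
DenseNet121,Exp3,GELU,SELU,0
DenseNet121,Exp3,GELU,Mish,0
DenseNet121,Exp3,GELU,SiLU,2
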