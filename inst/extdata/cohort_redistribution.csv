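model,category,cushion,mean,ci_lower,ci_upper,label
elliptical,SkinProtection,ActaEmbrace,0.50,0.49,0.50,Moderate
elliptical,SkinProtection,GelProElite,0.50,0.49,0.51,Moderate
elliptical,SkinProtection,GeoMattPRT,0.47,0.47,0.48,High
elliptical,SkinProtection,J2,0.46,0.45,0.47,High
elliptical,SkinProtection,MatrxVI,0.50,0.49,0.51,Moderate
elliptical,SkinProtection,RideForward,0.42,0.41,0.42,High
elliptical,GeneralUse,Amara100,0.55,0.55,0.56,Low
elliptical,GeneralUse,CrossCut,0.53,0.53,0.54,Low
elliptical,GeneralUse,GelUSeatLite,0.52,0.51,0.52,Low
elliptical,GeneralUse,MedlineGel,0.50,0.49,0.51,Moderate
elliptical,Reference,HR45_3in,0.50,0.49,0.50,Moderate
elliptical,Reference,HR45_2in,0.52,0.51,0.53,Low
trigonometric,SkinProtection,ActaEmbrace,0.58,0.57,0.58,Low
trigonometric,SkinProtection,GelProElite,0.57,0.56,0.58,Low
trigonometric,SkinProtection,GeoMattPRT,0.60,0.59,0.61,Low
trigonometric,SkinProtection,J2,0.53,0.53,0.54,High
trigonometric,SkinProtection,MatrxVI,0.57,0.57,0.58,Low
trigonometric,SkinProtection,RideForward,0.52,0.52,0.53,High
trigonometric,GeneralUse,Amara100,0.60,0.59,0.61,Low
trigonometric,GeneralUse,CrossCut,0.67,0.65,0.69,Low
trigonometric,GeneralUse,GelUSeatLite,0.54,0.53,0.54,High
trigonometric,GeneralUse,MedlineGel,0.69,0.68,0.71,Low
trigonometric,Reference,HR45_3in,0.57,0.56,0.57,Low
trigonometric,Reference,HR45_2in,0.64,0.63,0.66,Low
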